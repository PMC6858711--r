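#' Ordinal density score from a positive-cell fraction
#'
#' Maps the percentage of positive cells to the four-level score used for
#' CD8/CD163 read-outs: 0 absent; 1+ mild (< 10%); 2+ moderate (10-50%);
#' 3+ marked (50-100%). Cut-points are left-closed: exactly 10 scores 2+,
#' exactly 50 scores 3+ (the printed category bounds overlap at 50 and need
#' a convention). Vectorised; NA propagates.
#'
#' @param positive_fraction_pct numeric in \[0, 100\].
#' @return integer score(s) in 0:3.
#' @export
score_density <- function(positive_fraction_pct) {
  x <- as.numeric(positive_fraction_pct)
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad))
    stop("positive fraction must lie in [0, 100]; got ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  out[ok] <- ifelse(x[ok] == 0, 0L,
                    ifelse(x[ok] < 10, 1L, ifelse(x[ok] < 50, 2L, 3L)))
  out
}

#' Dichotomize an ordinal density score
#'
#' High = score 2+ or 3+; low = 0 or 1+.
#'
#' @param score integer score(s) in 0:3 (NA allowed).
#' @return factor with levels `low`, `high`.
#' @export
dichotomize_score <- function(score) {
  s <- as.integer(score)
  if (any(!is.na(s) & !s %in% 0:3))
    stop("scores must lie in 0:3", call. = FALSE)
  factor(ifelse(s >= 2L, "high", "low"), levels = c("low", "high"))
}

norm_dichot <- function(x, name) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "high", "low")
  if (any(!is.na(x) & !x %in% c("low", "high")))
    stop(sprintf("`%s` must be 'low'/'high'", name), call. = FALSE)
  x
}

#' CD8 x CD163 combination group
#'
#' Three-group combination of the dichotomized CD8 and CD163 read-outs in
#' one compartment: group 1 = high CD8 / low CD163; group 2 = both high or
#' both low; group 3 = low CD8 / high CD163. Group 3 (immune-excluded,
#' myeloid-rich) is the reference in the association models. Missing input
#' gives NA (not evaluable).
#'
#' @param cd8_dichot,cd163_dichot `"low"`/`"high"` (factor, character or
#'   logical with TRUE = high).
#' @return factor with levels `"1"`, `"2"`, `"3"`.
#' @export
combine_cd8_cd163 <- function(cd8_dichot, cd163_dichot) {
  cd8 <- norm_dichot(cd8_dichot, "cd8_dichot")
  cd163 <- norm_dichot(cd163_dichot, "cd163_dichot")
  g <- ifelse(cd8 == "high" & cd163 == "low", "1",
       ifelse(cd8 == "low" & cd163 == "high", "3", "2"))
  factor(g, levels = c("1", "2", "3"))
}

#' CD8 x PD-L1 combination group
#'
#' Group 1 = PD-L1 >= 5% and low CD8; group 2 = PD-L1 >= 5% and high CD8,
#' or PD-L1 < 5% and low CD8; group 3 = PD-L1 < 5% and high CD8.
#'
#' @param pdl1_pct percent PD-L1-positive tumor cells (NA = not evaluable).
#' @param cd8_dichot `"low"`/`"high"`.
#' @param cutoff_pct positivity cut-off (default 5%).
#' @return factor with levels `"1"`, `"2"`, `"3"`.
#' @export
combine_cd8_pdl1 <- function(pdl1_pct, cd8_dichot, cutoff_pct = 5) {
  cd8 <- norm_dichot(cd8_dichot, "cd8_dichot")
  pos <- pdl1_pct >= cutoff_pct
  g <- ifelse(pos & cd8 == "low", "1",
       ifelse(!pos & cd8 == "high", "3", "2"))
  factor(g, levels = c("1", "2", "3"))
}

#' CD8 x beta-catenin combination group
#'
#' Group 1 = low CD8 and beta-catenin overexpressed; group 2 = high CD8 and
#' overexpressed, or low CD8 and not overexpressed; group 3 = high CD8 and
#' not overexpressed.
#'
#' @param bcat_over logical, beta-catenin overexpressed (NA = not
#'   evaluable).
#' @param cd8_dichot `"low"`/`"high"`.
#' @return factor with levels `"1"`, `"2"`, `"3"`.
#' @export
combine_cd8_bcat <- function(bcat_over, cd8_dichot) {
  cd8 <- norm_dichot(cd8_dichot, "cd8_dichot")
  over <- as.logical(bcat_over)
  g <- ifelse(over & cd8 == "low", "1",
       ifelse(!over & cd8 == "high", "3", "2"))
  factor(g, levels = c("1", "2", "3"))
}

#' Dichotomize tumor-cell markers of a cohort
#'
#' Adds positivity flags for checkpoint ligands and beta-catenin to a
#' per-patient table: `pdl1_pos`/`pdl2_pos` use a fixed percentage cut-off
#' (>= 5% by default); `bcat_over` compares membranous beta-catenin to the
#' cohort median (strict `>`, computed over evaluable patients), or to a
#' fixed override such as a training-cohort median. Not-evaluable (NA)
#' percentages propagate to NA flags.
#'
#' @param cohort data.frame with any of `pdl1_pct`, `pdl2_pct`,
#'   `bcat_membranous_pct` (percent, NA = not evaluable).
#' @param pdl_cutoff_pct PD-L1/PD-L2 positivity cut-off.
#' @param bcat_cutoff_pct fixed beta-catenin cut-off; `NULL` (default) uses
#'   the cohort median.
#' @return the cohort with flag columns added; the cut-offs used are
#'   attached as attribute `cutoffs`.
#' @export
dichotomize_tumor_markers <- function(cohort, pdl_cutoff_pct = 5,
                                      bcat_cutoff_pct = NULL) {
  cohort <- as.data.frame(cohort)
  cuts <- list(pdl = pdl_cutoff_pct)
  chk <- function(col) {
    x <- cohort[[col]]
    if (all(is.na(x)))
      stop("marker column `", col, "` has no evaluable values", call. = FALSE)
    if (any(!is.na(x) & (x < 0 | x > 100)))
      stop("`", col, "` must lie in [0, 100]", call. = FALSE)
    x
  }
  if ("pdl1_pct" %in% names(cohort))
    cohort$pdl1_pos <- chk("pdl1_pct") >= pdl_cutoff_pct
  if ("pdl2_pct" %in% names(cohort))
    cohort$pdl2_pos <- chk("pdl2_pct") >= pdl_cutoff_pct
  if ("bcat_membranous_pct" %in% names(cohort)) {
    x <- chk("bcat_membranous_pct")
    cut <- if (is.null(bcat_cutoff_pct)) median(x, na.rm = TRUE)
           else bcat_cutoff_pct
    cohort$bcat_over <- x > cut
    cuts$bcat <- cut
  }
  attr(cohort, "cutoffs") <- cuts
  cohort
}
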