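#' Classify persistent post-concussion symptoms (PPCS)
#'
#' Summed symptom scores are offset by a pseudo-count, base-10
#' log-transformed, standardized against the healthy-control distribution of
#' the same transform, and thresholded: a patient is labeled PPCS when the
#' resulting z-score strictly exceeds `threshold` (default 1.64, the upper
#' 5% normal quantile).
#'
#' @param patient_scores Summed patient symptom scores at follow-up (>= 0).
#' @param hc_scores Summed healthy-control scores at follow-up (n >= 10).
#' @param threshold z cutoff (default 1.64).
#' @param pseudo Offset added before the log (default 1; symptom sums of 0
#'   occur).
#' @param ids Optional patient ids.
#' @return Data frame `sample_id`, `z_score`, `label` (`"PPCS"` /
#'   `"recovered"`), with attributes `hc_mean`, `hc_sd` (log10-scale
#'   anchors).
#' @export
classify_ppcs <- function(patient_scores, hc_scores, threshold = 1.64,
                          pseudo = 1, ids = NULL) {
  stopifnot(length(hc_scores) >= 10, all(patient_scores >= 0),
            all(hc_scores >= 0))
  t_hc <- log10(hc_scores + pseudo)
  hc_mean <- mean(t_hc)
  hc_sd <- stats::sd(t_hc)
  if (hc_sd == 0) stop("healthy-control scores have zero variance")
  z <- (log10(patient_scores + pseudo) - hc_mean) / hc_sd
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(patient_scores))
  structure(data.frame(sample_id = ids, z_score = z,
                       label = ifelse(z > threshold, "PPCS", "recovered"),
                       stringsAsFactors = FALSE),
            hc_mean = hc_mean, hc_sd = hc_sd, threshold = threshold,
            pseudo = pseudo)
}

#' ROC curve and AUC of a score against PPCS labels
#'
#' Threshold sweep over the unique score values with trapezoid integration;
#' equal scores are grouped, so the AUC equals the Mann-Whitney probability
#' of correct ranking with ties counted 1/2. For outcomes where a lower
#' score indicates PPCS (quality of life), use `direction =
#' "lower_is_ppcs"`.
#'
#' @param scores Predicted outcome values.
#' @param labels Logical, 0/1, or `"PPCS"`/`"recovered"` labels.
#' @param direction `"higher_is_ppcs"` (default) or `"lower_is_ppcs"`.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels,
                    direction = c("higher_is_ppcs", "lower_is_ppcs")) {
  direction <- match.arg(direction)
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "PPCS"
  } else as.logical(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  s <- if (direction == "lower_is_ppcs") -scores else scores
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- tapply(pos, grp, sum)
  fp <- tapply(!pos, grp, sum)
  tpr <- c(0, cumsum(tp)) / sum(pos)
  fpr <- c(0, cumsum(fp)) / sum(!pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, s[!duplicated(s)]),
                        fpr = fpr, tpr = tpr),
       auc = auc)
}
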