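# Expert-concordance evaluation: deviation distances of RF marking points
# from the grid-centered origin, per-group metrics, and the three-tier
# quality classification.

#' Deviation distances from the grid center
#'
#' @param points N x 2 matrix (or data frame with x/y columns) of marking
#'   positions in grid-centered mm coordinates.
#' @return Numeric vector of Euclidean distances.
#' @export
deviation_distances <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 1) stop("need at least one point")
  sqrt(rowSums(pts^2))
}

#' Per-group concordance metrics
#'
#' Mean deviation, sample SD (n - 1 denominator), coefficient of variation
#' CV = 100 * SD / mean (%), and the percentage of deviations within the
#' 2 mm clinical threshold.
#'
#' @param distances Deviation distances (mm), n >= 2.
#' @return List of class `group_metrics`: `n`, `mean_dev`, `sd_dev`, `cv`,
#'   `pct_within_2mm`.
#' @export
group_metrics <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) < 2) stop("need at least 2 distances")
  m <- mean(d)
  if (m == 0) stop("mean deviation is zero; CV undefined")
  structure(list(n = length(d), mean_dev = m, sd_dev = sd(d),
                 cv = 100 * sd(d) / m,
                 pct_within_2mm = 100 * mean(d <= 2)),
            class = "group_metrics")
}

#' Three-tier quality classification
#'
#' excellent: CV below 15% and within-2 mm percentage above 90%;
#' acceptable: CV between 15 and 20% and within-2 mm percentage between 80
#' and 90%; otherwise needs improvement. Boundary values (CV exactly 15 or
#' 20, percentage exactly 80 or 90) are assigned to the acceptable tier.
#' In CV-only mode the percentage criterion is ignored (the same CV cuts
#' apply), for data sets where only mean and SD are published.
#'
#' @param m A [group_metrics()] result (or a list with `cv` and optionally
#'   `pct_within_2mm`).
#' @param cv_only Classify on CV alone.
#' @return `"excellent"`, `"acceptable"` or `"needs_improvement"`.
#' @export
classify_group <- function(m, cv_only = FALSE) {
  cv <- m$cv
  if (cv_only) {
    if (cv < 15) return("excellent")
    if (cv <= 20) return("acceptable")
    return("needs_improvement")
  }
  pct <- m$pct_within_2mm
  if (cv < 15 && pct > 90) return("excellent")
  if (cv >= 15 && cv <= 20 && pct >= 80 && pct <= 90) return("acceptable")
  "needs_improvement"
}

#' Summary report over groups
#'
#' Per-category counts and percentages (one decimal) plus the pooled range
#' of group mean deviations.
#'
#' @param metrics List of [group_metrics()] results.
#' @param categories Optional precomputed categories (otherwise
#'   [classify_group()] is applied).
#' @param cv_only Passed to [classify_group()].
#' @return List with `n_groups`, `counts`, `percentages`, `categories`,
#'   `mean_dev_range`.
#' @export
summarize_groups <- function(metrics, categories = NULL, cv_only = FALSE) {
  if (length(metrics) < 1) stop("need at least one group")
  if (is.null(categories))
    categories <- vapply(metrics, classify_group, character(1),
                         cv_only = cv_only)
  lv <- c("excellent", "acceptable", "needs_improvement")
  counts <- table(factor(categories, levels = lv))
  pct <- round(100 * as.numeric(counts) / length(categories), 1)
  names(pct) <- lv
  means <- vapply(metrics, function(m) m$mean_dev, numeric(1))
  list(n_groups = length(metrics), counts = counts, percentages = pct,
       categories = categories, mean_dev_range = range(means))
}

#' Evaluate a marking-point table
#'
#' @param marks Data frame with columns `group_id`, `x_mm`, `y_mm` (one row
#'   per RF marking) or a CSV path to one.
#' @return List with per-group [group_metrics()] (`metrics`), categories,
#'   and the [summarize_groups()] report.
#' @export
evaluate_concordance <- function(marks) {
  if (is.character(marks)) marks <- read.csv(marks)
  need <- c("group_id", "x_mm", "y_mm")
  if (!all(need %in% names(marks)))
    stop("marks must have columns group_id, x_mm, y_mm")
  groups <- split(marks, marks$group_id)
  metrics <- lapply(groups, function(g)
    group_metrics(deviation_distances(cbind(g$x_mm, g$y_mm))))
  categories <- vapply(metrics, classify_group, character(1))
  list(metrics = metrics, categories = categories,
       summary = summarize_groups(metrics, categories))
}

#' Published expert-group summary statistics
#'
#' Mean and SD of the RF-marking deviation distances (mm) for the seven
#' expert groups of the reference evaluation, as printed in its summary
#' figure; the raw marking coordinates are not public. With CV-only
#' classification these reproduce the published three-tier partition.
#'
#' @return Data frame with `group`, `mean_dev_mm`, `sd_dev_mm`.
#' @export
expert_group_summary <- function() {
  path <- system.file("extdata", "expert_groups.csv", package = "condylenav")
  read.csv(path)
}
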