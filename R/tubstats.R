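# Tubulation-efficiency statistic and group comparison.
#
# The per-image statistic is the ratio of total tubule area over total
# membrane (tubule + vesicle) area, computed after shape-criteria
# reassignment.  Images are the unit of replication: ratios are computed
# per image and then averaged within a condition.

#' Tubulation efficiency of one image
#'
#' @param objects object table from [extract_objects()] (after
#'   [reassign_by_shape()]) for a single image.
#' @param image_id identifier recorded in the result.
#' @return a `tubulation_result`: list with `image_id`, `tubule_area_nm2`,
#'   `vesicle_area_nm2`, `ratio` (NA and `defined = FALSE` when the image
#'   contains no foreground objects at all — such images are excluded from
#'   aggregation rather than counted as 0).
#' @export
tubulation_ratio <- function(objects, image_id = NA_character_) {
  at <- sum(objects$area_nm2[objects$class == "tubule"])
  av <- sum(objects$area_nm2[objects$class == "vesicle"])
  defined <- (at + av) > 0
  structure(list(image_id = image_id,
                 tubule_area_nm2 = at, vesicle_area_nm2 = av,
                 ratio = if (defined) at / (at + av) else NA_real_,
                 defined = defined),
            class = "tubulation_result")
}

#' @export
print.tubulation_result <- function(x, ...) {
  cat(sprintf("<tubulation_result> image %s: ratio %s\n", x$image_id,
              if (x$defined) sprintf("%.4f", x$ratio) else "undefined"))
  invisible(x)
}

#' Summarize tubulation ratios for one condition
#'
#' Mean and sample SD (n - 1 denominator) over the defined per-image
#' ratios; a single-image group gets SD 0 by convention.
#'
#' @param results list of [tubulation_ratio()] results, or a numeric vector
#'   of ratios.
#' @param label condition label.
#' @return a `group_summary` with `label`, `ratios`, `mean`, `sd`, `n`.
#' @export
summarize_group <- function(results, label = "") {
  ratios <- if (is.numeric(results)) results else
    vapply(results, function(r) r$ratio, 0)
  ratios <- ratios[!is.na(ratios)]
  n <- length(ratios)
  if (n < 1L) stop("group '", label, "' has no defined tubulation ratios")
  structure(list(label = label, ratios = ratios, mean = mean(ratios),
                 sd = if (n > 1L) stats::sd(ratios) else 0, n = n),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: mean %.4f +/- SD %.4f (n = %d)\n",
              x$label, x$mean, x$sd, x$n))
  invisible(x)
}

#' Compare tubulation between conditions
#'
#' Two groups: two-sided Welch (unequal-variance) t test.  More than two:
#' ordinary (fixed-effects) one-way ANOVA F test.  `method = "t_test"` or
#' `"anova"` forces the choice ("t_test" additionally accepts
#' `var_equal = TRUE` for the pooled-variance Student test).
#'
#' @param groups list of [summarize_group()] objects or of numeric ratio
#'   vectors (>= 2 groups, each with n >= 2).
#' @param method `"auto"` (default), `"t_test"` or `"anova"`.
#' @param var_equal for the t test, assume equal variances (default FALSE,
#'   i.e. Welch).
#' @return list with `method`, `statistic`, `df` (length 2 for ANOVA),
#'   `p_value`, `group_labels`.
#' @export
compare_groups <- function(groups, method = c("auto", "t_test", "anova"),
                           var_equal = FALSE) {
  method <- match.arg(method)
  vals <- lapply(groups, function(g)
    if (inherits(g, "group_summary")) g$ratios else as.numeric(g))
  labels <- vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (inherits(g, "group_summary") && nzchar(g$label)) g$label
    else paste0("group", i)
  }, "")
  k <- length(vals)
  if (k < 2L) stop("need at least two groups")
  if (any(vapply(vals, length, 0L) < 2L))
    stop("every group needs n >= 2")
  if (method == "auto") method <- if (k == 2L) "t_test" else "anova"
  if (method == "t_test") {
    if (k != 2L) stop("t test requires exactly two groups")
    tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = var_equal)
    list(method = if (var_equal) "student_t" else "welch_t",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, group_labels = labels)
  } else {
    x <- unlist(vals)
    g <- factor(rep(labels, times = vapply(vals, length, 0L)))
    fit <- stats::oneway.test(x ~ g, var.equal = TRUE)  # ordinary ANOVA
    list(method = "anova",
         statistic = unname(fit$statistic),
         df = unname(fit$parameter), p_value = fit$p.value,
         group_labels = labels)
  }
}
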