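#' Relative quantification by the 2^-ddCt method
#'
#' Technical-replicate Ct values are averaged per (sample, gene); per
#' sample and target gene, `dCt = mean Ct_target - mean Ct_reference`;
#' `ddCt = dCt - mean(dCt over the calibrator group)`; the fold change is
#' `2^-ddCt`. By construction the geometric mean fold of the calibrator
#' group is exactly 1.
#'
#' @param records tidy Ct tibble (`sample_id`, `group`, `gene`, `ct`; one
#'   row per technical replicate).
#' @param reference_gene name of the internal reference gene, present for
#'   every sample.
#' @param calibrator_group the `group` value used as calibrator.
#' @return A tibble (`sample_id`, `group`, `gene`, `dct`, `ddct`, `fold`)
#'   with one row per sample and target gene.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("a1", "b1"), each = 2),
#'   group = rep(c("A", "B"), each = 2),
#'   gene = rep(c("tgt", "ref"), 2),
#'   ct = c(25, 18, 24, 18)
#' )
#' ddct(ct, "ref", "A") # group B fold = 2
ddct <- function(records, reference_gene, calibrator_group) {
  need <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(sprintf("Ct table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!calibrator_group %in% records$group) {
    abort(sprintf("calibrator group '%s' not present", calibrator_group))
  }
  if (any(!is.finite(records$ct))) abort("Ct values must be finite")
  mean_ct <- records |>
    group_by(.data$sample_id, .data$group, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- mean_ct |>
    filter(.data$gene == reference_gene) |>
    select("sample_id", ref_ct = "ct")
  no_ref <- setdiff(unique(mean_ct$sample_id), ref$sample_id)
  if (length(no_ref) > 0) {
    abort(sprintf(
      "sample(s) missing the reference gene '%s': %s",
      reference_gene, paste(head(no_ref, 5), collapse = ", ")
    ))
  }
  dct <- mean_ct |>
    filter(.data$gene != reference_gene) |>
    left_join(ref, by = "sample_id") |>
    mutate(dct = .data$ct - .data$ref_ct)
  dct |>
    group_by(.data$gene) |>
    mutate(
      ddct = .data$dct - mean(.data$dct[.data$group == calibrator_group]),
      fold = 2^(-.data$ddct)
    ) |>
    ungroup() |>
    select("sample_id", "group", "gene", "dct", "ddct", "fold")
}

#' Relative dual-luciferase activity
#'
#' Per replicate, activity is the reporter/normalizer channel ratio; the
#' relative activity of a construct is the mean mimic activity divided by
#' the mean negative-control (NC) activity. Channel roles are named
#' explicitly in the input rather than tied to firefly/Renilla, since
#' which enzyme carries the cloned site depends on the vector design.
#'
#' @param records tibble (`construct`, `treatment` in mimic/NC,
#'   `replicate`, `reporter`, `normalizer`), readings > 0.
#' @return A list: `relative` (tibble `construct`, `relative_activity`) and
#'   `replicates` (tibble `construct`, `treatment`, `replicate`,
#'   `activity`).
#' @export
luciferase_relative <- function(records) {
  need <- c("construct", "treatment", "replicate", "reporter", "normalizer")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(sprintf("luciferase table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(records$normalizer <= 0)) abort("normalizer readings must be > 0")
  if (any(records$reporter <= 0)) abort("reporter readings must be > 0")
  if (!all(records$treatment %in% c("mimic", "NC"))) {
    abort("treatment must be 'mimic' or 'NC'")
  }
  reps <- records |>
    mutate(activity = .data$reporter / .data$normalizer) |>
    select("construct", "treatment", "replicate", "activity")
  relative <- reps |>
    group_by(.data$construct, .data$treatment) |>
    summarise(mean_activity = mean(.data$activity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "mean_activity") |>
    mutate(relative_activity = .data$mimic / .data$NC) |>
    select("construct", "relative_activity")
  list(relative = relative, replicates = reps)
}

#' One-way ANOVA with significance stars
#'
#' Classical one-way analysis of variance (F with `k - 1` and `N - k`
#' degrees of freedom) followed by the conventional star labelling:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise. When both the between- and within-group sums of squares are
#' zero (all values identical) the test is vacuous and returns `F = 0`,
#' `p = 1`, `ns`.
#'
#' @param data a data frame.
#' @param value name of the numeric response column (default "value").
#' @param group name of the grouping column (default "group").
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `stars`.
#' @export
#' @examples
#' one_way_anova(data.frame(
#'   value = c(1, 2, 3, 8, 9, 10),
#'   group = rep(c("a", "b"), each = 3)
#' ))
one_way_anova <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 values")
  df_b <- nlevels(g) - 1L
  df_w <- length(v) - nlevels(g)
  if (stats::var(v) == 0) {
    return(tibble(
      statistic = 0, df_between = df_b, df_within = df_w,
      p_value = 1, stars = "ns"
    ))
  }
  fit <- anova(aov(v ~ g))
  f <- fit$`F value`[1]
  p <- fit$`Pr(>F)`[1]
  tibble(
    statistic = f, df_between = df_b, df_within = df_w,
    p_value = p, stars = star_label(p)
  )
}
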