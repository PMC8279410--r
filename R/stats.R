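#' log(x + 1) transform for RSA values
#'
#' The +1 shift accommodates exact zeros (fully buried residues) and reduces
#' the right skew of RSA before rank-based testing. Negative input — in
#' particular an unfiltered `-1` unresolved-residue sentinel — is an error,
#' signalling a missed exclusion upstream.
#'
#' @param values numeric vector, all >= 0.
#' @return `log(values + 1)` (natural log).
#' @export
log1p_transform <- function(values) {
  if (any(is.na(values))) stop("missing RSA values must be excluded upstream")
  if (any(values < 0)) {
    stop("negative RSA input (unfiltered sentinel?): ",
         paste(utils::head(values[values < 0]), collapse = ", "))
  }
  log1p(values)
}

.check_groups <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  empty <- vapply(groups, length, 0L) == 0L
  if (any(empty)) {
    stop("empty group(s): ", paste(names(groups)[empty], collapse = ", "))
  }
  groups
}

#' Kruskal-Wallis test across variant groups
#'
#' Tie-corrected H statistic with the chi-squared approximation
#' (df = number of groups - 1).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each nonempty).
#' @param stratum label carried into the result (e.g. a domain name).
#' @return list of class `kw_result`: `H`, `df`, `p`, `n_per_group`,
#'   `stratum`.
#' @export
kruskal_wallis <- function(groups, stratum = "full_protein") {
  groups <- .check_groups(groups)
  if (length(groups) < 2L) stop("need at least two groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  kt <- stats::kruskal.test(values, g)
  structure(
    list(
      H = unname(kt$statistic),
      df = unname(kt$parameter),
      p = kt$p.value,
      n_per_group = vapply(groups, length, 0L),
      stratum = stratum
    ),
    class = "kw_result"
  )
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis [%s]: H = %.4g, df = %d, p = %.3g (n: %s)\n",
              x$stratum, x$H, x$df, x$p,
              paste(names(x$n_per_group), x$n_per_group, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum test for every unordered pair of groups. Exact
#' enumeration is used when both groups are small (min n <= `exact_max`) and
#' there are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction. Adjusted p-values are `min(1, m * p_raw)` with m =
#' number of pairs.
#'
#' @param groups named list of numeric vectors.
#' @param stratum label carried into the result.
#' @param exact_max largest group size for which exact enumeration is used.
#' @return list of class `pairwise_result`: `comparisons` data.frame
#'   (`group_a`, `group_b`, `W`, `p_raw`, `p_adjusted`), `correction`, `m`,
#'   `stratum`.
#' @export
pairwise_wilcoxon_bonferroni <- function(groups, stratum = "full_protein",
                                         exact_max = 10L) {
  groups <- .check_groups(groups)
  if (length(groups) < 2L) stop("need at least two groups")
  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- groups[[pairs[1L, k]]]
    b <- groups[[pairs[2L, k]]]
    use_exact <- min(length(a), length(b)) <= exact_max &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                         alternative = "two.sided")
    )
    data.frame(
      group_a = pairs[1L, k], group_b = pairs[2L, k],
      W = unname(wt$statistic), p_raw = wt$p.value,
      p_adjusted = min(1, m * wt$p.value),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(comparisons = do.call(rbind, rows), correction = "bonferroni",
         m = m, stratum = stratum),
    class = "pairwise_result"
  )
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("Pairwise Wilcoxon [%s], Bonferroni m = %d:\n", x$stratum, x$m))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

.split_by_group <- function(table, value_col = "rsa") {
  split(table[[value_col]], table$group)
}

#' Domain-stratified group comparison
#'
#' Runs the Kruskal-Wallis test and pairwise Wilcoxon tests within each
#' stratum (protein domain, plus `"full_protein"` = all rows). Strata in which
#' any group has zero observations are skipped with a log entry rather than
#' an error.
#'
#' @param table annotated variant table (columns `group`, `domain`, `rsa`).
#' @param strata character vector of strata; defaults to `"full_protein"`
#'   plus every domain present in the table.
#' @param transform `"log1p"` (default, see [log1p_transform()]) or `"none"`.
#'   Rank-based statistics are invariant to this monotone transform; it is
#'   applied for consistency of exported values.
#' @return list of class `stratified_result`: per-stratum list with `kruskal`
#'   and `pairwise` entries; attribute `skipped` records strata not tested.
#' @export
stratified_compare <- function(table, strata = NULL,
                               transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  stopifnot(all(c("group", "domain", "rsa") %in% names(table)))
  vals <- if (transform == "log1p") log1p_transform(table$rsa) else table$rsa
  table$.value <- vals
  if (is.null(strata)) {
    strata <- c("full_protein", sort(unique(table$domain)))
  }
  groups_all <- sort(unique(table$group))
  out <- list()
  skipped <- data.frame(stratum = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (s in strata) {
    sub <- if (s == "full_protein") table else table[table$domain == s, ]
    counts <- table(factor(sub$group, levels = groups_all))
    if (any(counts == 0L)) {
      skipped <- rbind(skipped, data.frame(
        stratum = s,
        reason = paste0("no observations in group(s): ",
                        paste(names(counts)[counts == 0L], collapse = ", ")),
        stringsAsFactors = FALSE))
      next
    }
    gl <- split(sub$.value, sub$group)
    out[[s]] <- list(
      kruskal = kruskal_wallis(gl, stratum = s),
      pairwise = pairwise_wilcoxon_bonferroni(gl, stratum = s)
    )
  }
  structure(out, class = "stratified_result", skipped = skipped,
            transform = transform)
}

.auc_midrank <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))  # midranks under ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve and AUC for RSA as a pathogenicity score
#'
#' Scores each variant as `-RSA` (buried residues score high), so a predictor
#' in which disease variants are more buried than population variants yields
#' AUC > 0.5. AUC is the midrank Mann-Whitney probability that a random
#' positive outscores a random negative; ROC points come from a threshold
#' sweep with tied scores grouped.
#'
#' @param table annotated variant table (columns `group`, `rsa`).
#' @param positive_group disease group treated as positive (e.g. `"NDD"` or
#'   `"cancer"`).
#' @param negative_group background group (default `"population"`).
#' @return list of class `roc_result`: `points` (data.frame `fpr`, `tpr`),
#'   `auc`, `positive_label`, `negative_label`, `n_positive`, `n_negative`,
#'   `score_orientation = "low_rsa_is_positive"`.
#' @export
roc_auc <- function(table, positive_group, negative_group = "population") {
  stopifnot(all(c("group", "rsa") %in% names(table)))
  pos <- table$rsa[table$group == positive_group]
  neg <- table$rsa[table$group == negative_group]
  if (!length(pos)) stop("positive group '", positive_group, "' is empty")
  if (!length(neg)) stop("negative group '", negative_group, "' is empty")
  pos_s <- -pos
  neg_s <- -neg
  auc <- .auc_midrank(pos_s, neg_s)
  # threshold sweep, descending unique scores, ties grouped
  thr <- sort(unique(c(pos_s, neg_s)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_s >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg_s >= t), 0)
  points <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  points <- unique(points)
  structure(
    list(points = points, auc = auc,
         positive_label = positive_group, negative_label = negative_group,
         n_positive = length(pos), n_negative = length(neg),
         score_orientation = "low_rsa_is_positive"),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC %s (n=%d) vs %s (n=%d): AUC = %.4f [score orientation: %s]\n",
    x$positive_label, x$n_positive, x$negative_label, x$n_negative,
    x$auc, x$score_orientation))
  invisible(x)
}

#' Export ROC points as a two-column table
#'
#' @param roc a [roc_auc()] result.
#' @param path output file (tab-delimited, columns `fpr`, `tpr`).
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
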