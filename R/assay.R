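#' Read an immunoblot quantification table
#'
#' Tab- or comma-delimited densitometry table with one row per lane:
#' `construct_id`, `replicate_id`, `readout`, `phospho_signal`,
#' `total_signal`, optional `expression_signal`.
#'
#' @param path file path.
#' @return data.frame of blot measurements.
#' @export
read_blot_table <- function(path) {
  if (!file.exists(path)) stop("blot table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("construct_id", "replicate_id", "readout",
              "phospho_signal", "total_signal")
  if (!all(needed %in% names(df))) {
    stop("blot table needs columns: ", paste(needed, collapse = ", "))
  }
  df
}

#' Phospho/total activity ratios normalized to wild-type
#'
#' For every lane, `raw_ratio = phospho_signal / total_signal`; the
#' `relative_ratio` divides by the wild-type lane's raw ratio of the same
#' replicate and readout, so the wild-type relative ratio is exactly 1 in
#' every replicate. Normalization per blot removes between-blot scale
#' (exposure, transfer efficiency).
#'
#' @param measurements data.frame in the [read_blot_table()] schema.
#' @param wt_id construct identifier of the wild-type lane (default `"WT"`).
#' @return data.frame with columns `construct_id`, `replicate_id`, `readout`,
#'   `raw_ratio`, `relative_ratio`.
#' @export
compute_ratios <- function(measurements, wt_id = "WT") {
  needed <- c("construct_id", "replicate_id", "readout",
              "phospho_signal", "total_signal")
  stopifnot(all(needed %in% names(measurements)))
  zero_tot <- measurements$total_signal <= 0
  if (any(zero_tot)) {
    bad <- measurements[zero_tot, ]
    stop("non-positive total signal in lane(s): ",
         paste(paste0(bad$construct_id, "/", bad$replicate_id),
               collapse = ", "))
  }
  key <- interaction(measurements$replicate_id, measurements$readout,
                     drop = TRUE)
  out <- lapply(split(measurements, key), function(rep_df) {
    wt <- rep_df[rep_df$construct_id == wt_id, , drop = FALSE]
    if (nrow(wt) != 1L) {
      stop("replicate '", rep_df$replicate_id[1L], "' (", rep_df$readout[1L],
           ") has ", nrow(wt), " wild-type lane(s); need exactly 1")
    }
    wt_ratio <- wt$phospho_signal / wt$total_signal
    if (wt_ratio <= 0) {
      stop("wild-type raw ratio <= 0 in replicate '",
           rep_df$replicate_id[1L], "'")
    }
    raw <- rep_df$phospho_signal / rep_df$total_signal
    data.frame(
      construct_id = rep_df$construct_id,
      replicate_id = rep_df$replicate_id,
      readout = rep_df$readout,
      raw_ratio = raw,
      relative_ratio = raw / wt_ratio,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired tests of construct activity against wild-type
#'
#' Per construct and readout, a two-sided paired Student t-test of the
#' per-replicate relative ratios against the wild-type value of 1 (pairing is
#' within blot; the per-blot normalization makes the wild-type member of each
#' pair exactly 1). Bonferroni correction over the constructs tested in the
#' batch. Constructs with fewer than 2 paired replicates are summarized
#' without test fields; a zero-variance difference is reported with
#' `degenerate_variance = TRUE` and p at the machine floor.
#'
#' @param ratios data.frame from [compute_ratios()].
#' @param constructs constructs to test; defaults to all non-wild-type
#'   constructs present.
#' @param wt_id wild-type construct identifier.
#' @return data.frame of class `construct_summary`: `construct_id`, `readout`,
#'   `n_replicates`, `mean_relative_ratio`, `t_statistic`, `p_raw`,
#'   `p_adjusted`, `degenerate_variance`, attribute `m` (Bonferroni family
#'   size).
#' @export
test_vs_wildtype <- function(ratios, constructs = NULL, wt_id = "WT") {
  stopifnot(all(c("construct_id", "replicate_id", "readout",
                  "relative_ratio") %in% names(ratios)))
  if (is.null(constructs)) {
    constructs <- setdiff(unique(ratios$construct_id), wt_id)
  }
  combos <- unique(ratios[ratios$construct_id %in% constructs,
                          c("construct_id", "readout")])
  m <- nrow(combos)
  rows <- lapply(seq_len(m), function(k) {
    cid <- combos$construct_id[k]
    ro <- combos$readout[k]
    rel <- ratios$relative_ratio[ratios$construct_id == cid &
                                   ratios$readout == ro]
    n <- length(rel)
    base <- data.frame(
      construct_id = cid, readout = ro, n_replicates = n,
      mean_relative_ratio = mean(rel),
      t_statistic = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
      degenerate_variance = FALSE, stringsAsFactors = FALSE
    )
    if (n < 2L) return(base)
    d <- rel - 1
    # numerically constant differences (incl. exact replication of WT)
    if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
      base$degenerate_variance <- TRUE
      if (abs(mean(d)) <= 1e-10) {
        base$t_statistic <- 0
        base$p_raw <- 1
      } else {
        base$t_statistic <- sign(mean(d)) * Inf
        base$p_raw <- .Machine$double.xmin
      }
    } else {
      tt <- stats::t.test(rel, mu = 1, alternative = "two.sided")
      base$t_statistic <- unname(tt$statistic)
      base$p_raw <- tt$p.value
    }
    base$p_adjusted <- min(1, m * base$p_raw)
    base
  })
  if (!length(rows)) {
    out <- data.frame(
      construct_id = character(), readout = character(),
      n_replicates = integer(), mean_relative_ratio = numeric(),
      t_statistic = numeric(), p_raw = numeric(), p_adjusted = numeric(),
      degenerate_variance = logical(), stringsAsFactors = FALSE
    )
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  attr(out, "m") <- m
  class(out) <- c("construct_summary", "data.frame")
  out
}
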