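#' Per-target ranking loss
#'
#' For each target, the difference between the true quality of its best decoy
#' and the true quality of the decoy ranked first by predicted score.  Zero
#' means the method's top pick is a true-best decoy.  Ties in predicted score
#' are broken lexicographically by decoy id for reproducibility.  The metric
#' is agnostic to the quality scale: feeding TM-scores as `true_score`
#' evaluates TM-score ranking loss with the same code path.
#'
#' @param data a data frame with columns `decoy_id`, `true_score`,
#'   `pred_score`, and optionally `target_id` (grouped over when present).
#' @return a tibble with `target_id` (if present), `n_decoys`, `best_true`,
#'   `selected_true`, `ranking_loss`.
#' @export
ranking_loss <- function(data) {
  stopifnot(all(c("decoy_id", "true_score", "pred_score") %in% names(data)))
  if (nrow(data) == 0) stop("empty score table", call. = FALSE)
  stopifnot(all(is.finite(data$true_score)), all(is.finite(data$pred_score)))
  one <- function(d) {
    if (anyDuplicated(d$decoy_id)) {
      stop("duplicate decoy ids within a target", call. = FALSE)
    }
    sel <- d[order(-d$pred_score, d$decoy_id), ][1, ]
    tibble::tibble(n_decoys = nrow(d), best_true = max(d$true_score),
                   selected_true = sel$true_score,
                   ranking_loss = max(d$true_score) - sel$true_score)
  }
  if ("target_id" %in% names(data)) {
    data |>
      dplyr::group_by(.data$target_id) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(data)
  }
}

#' Top-N hit-rate triple per target
#'
#' Counts, among the top `n` decoys by predicted score, how many are of
#' Acceptable-or-higher (`a`), Medium-or-higher (`b`) and High (`c`) quality.
#' All rows are used when a target has fewer than `n` decoys.
#'
#' @param data a data frame with `decoy_id`, `pred_score`, `true_class`
#'   (factor or character over the four quality classes), optionally
#'   `target_id`.
#' @param n ranking depth (default 10).
#' @return a tibble with `target_id` (if present) and integer `a`, `b`, `c`.
#' @export
hit_rate <- function(data, n = 10) {
  stopifnot(all(c("decoy_id", "pred_score", "true_class") %in% names(data)))
  if (anyNA(data$true_class)) stop("missing true_class", call. = FALSE)
  one <- function(d) {
    top <- d[order(-d$pred_score, d$decoy_id), ]
    top <- top[seq_len(min(n, nrow(top))), ]
    lev <- match(as.character(top$true_class), QUALITY_CLASSES)
    if (anyNA(lev)) stop("unknown quality class", call. = FALSE)
    tibble::tibble(a = sum(lev >= 2), b = sum(lev >= 3), c = sum(lev >= 4))
  }
  if ("target_id" %in% names(data)) {
    data |>
      dplyr::group_by(.data$target_id) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(data)
  }
}

#' Summarise per-target ranking losses for one method
#'
#' Arithmetic mean, population (divide-by-n) standard deviation and the
#' count of exact-zero losses.  The population convention reproduces the
#' printed column dispersions of published benchmark tables.
#'
#' @param losses numeric vector of per-target losses, or a data frame with a
#'   `ranking_loss` column (e.g. from [ranking_loss()]).
#' @return a one-row tibble: `n_targets`, `mean_loss`, `sd_loss`, `n_zero`.
#' @export
summarize_losses <- function(losses) {
  if (is.data.frame(losses)) losses <- losses$ranking_loss
  stopifnot(length(losses) >= 1, all(is.finite(losses)))
  tibble::tibble(n_targets = length(losses), mean_loss = mean(losses),
                 sd_loss = sqrt(mean((losses - mean(losses))^2)),
                 n_zero = sum(losses == 0))
}

#' Count per-target lowest-loss winners across methods
#'
#' For each target the minimum loss across methods is found and every method
#' attaining it gets credit (ties count for all attainers).
#'
#' @param data either a wide data frame (`target_id` plus one numeric column
#'   per method) or a long one (`target_id`, `method`, `loss`).
#' @return a tibble `method`, `n_best`, ordered as the input methods.
#' @export
lowest_loss_winners <- function(data) {
  if (!"method" %in% names(data)) {
    stopifnot("target_id" %in% names(data))
    data <- tidyr::pivot_longer(data, -"target_id", names_to = "method",
                                values_to = "loss")
  }
  stopifnot(!anyNA(data$loss))
  counts <- table(data$target_id, data$method)
  if (any(counts != 1)) stop("ragged method x target table", call. = FALSE)
  data |>
    dplyr::group_by(.data$target_id) |>
    dplyr::mutate(is_best = .data$loss == min(.data$loss)) |>
    dplyr::ungroup() |>
    dplyr::group_by(method = factor(.data$method,
                                    levels = unique(.data$method))) |>
    dplyr::summarize(n_best = sum(.data$is_best), .groups = "drop")
}

#' Summarise per-target hit-rate triples for one method
#'
#' Counts the targets for which the method places at least one
#' Acceptable-or-higher, Medium-or-higher, and High-quality decoy in its
#' Top-N (i.e. targets with non-zero `a`, `b`, `c`).
#'
#' @param triples a data frame with integer columns `a`, `b`, `c` (one row
#'   per target), e.g. from [hit_rate()].
#' @return a one-row tibble: `n_targets`, `hit_acceptable`, `hit_medium`,
#'   `hit_high`.
#' @export
summarize_hit_rates <- function(triples) {
  stopifnot(all(c("a", "b", "c") %in% names(triples)), nrow(triples) >= 1)
  stopifnot(all(triples$a >= triples$b), all(triples$b >= triples$c),
            all(triples$c >= 0))
  tibble::tibble(n_targets = nrow(triples),
                 hit_acceptable = sum(triples$a > 0),
                 hit_medium = sum(triples$b > 0),
                 hit_high = sum(triples$c > 0))
}

#' Read a per-decoy score table
#'
#' CSV with columns `target_id`, `decoy_id`, `true_score`, optional
#' `true_class`, and `pred_score` — the unit of ranking evaluation.
#'
#' @param path CSV file (comment lines starting with `#` ignored).
#' @return a tibble.
#' @export
read_score_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("target_id", "decoy_id", "true_score", "pred_score")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("score table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Bundled DBM55-AF2 benchmark tables
#'
#' Published per-target results on the DBM55-AF2 decoy set (15 targets of
#' AlphaFold-Multimer decoys for Docking Benchmark 5.5 complexes):
#' `dbm55_ranking_losses()` gives the DockQ ranking loss of seven scoring
#' methods per target; `dbm55_hit_rates()` their Top-10 hit-rate triples
#' (columns `<method>_a/_b/_c`) plus the best-possible triple.  Shipped as
#' plain CSVs under `extdata/`.
#'
#' @return a tibble (wide, one row per target).
#' @export
dbm55_ranking_losses <- function() {
  readr::read_csv(system.file("extdata", "dbm55_af2_ranking_loss.csv",
                              package = "ggtqa"),
                  show_col_types = FALSE, comment = "#")
}

#' @rdname dbm55_ranking_losses
#' @export
dbm55_hit_rates <- function() {
  readr::read_csv(system.file("extdata", "dbm55_af2_hit_rates.csv",
                              package = "ggtqa"),
                  show_col_types = FALSE, comment = "#")
}

#' Benchmark summary report across methods
#'
#' Convenience wrapper reproducing the summary rows of a multi-method
#' ranking-loss table: per-method mean, population sd, zero-loss count and
#' tie-inclusive lowest-loss winner count.
#'
#' @param losses wide data frame: `target_id` plus one loss column per
#'   method.
#' @return a tibble, one row per method.
#' @export
summarize_benchmark <- function(losses) {
  winners <- lowest_loss_winners(losses)
  methods <- setdiff(names(losses), "target_id")
  purrr::map_dfr(methods, function(m) {
    s <- summarize_losses(losses[[m]])
    tibble::tibble(method = m, mean_loss = s$mean_loss, sd_loss = s$sd_loss,
                   n_zero = s$n_zero,
                   n_best = winners$n_best[winners$method == m])
  })
}
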