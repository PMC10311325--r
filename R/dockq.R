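# Scaling constants of the DockQ combination formula (Basu & Wallner 2016):
# iRMSD scaled by 1.5 A, LRMSD by 8.5 A.  Class thresholds 0.23 / 0.49 / 0.80
# come from the same reference; both are external, sourced constants.
DOCKQ_D1 <- 1.5
DOCKQ_D2 <- 8.5

QUALITY_CLASSES <- c("Incorrect", "Acceptable", "Medium", "High")

#' Default DockQ class thresholds
#'
#' Lower bounds of the Acceptable, Medium and High classes on the DockQ
#' scale.  Boundary convention: each lower bound is inclusive (a score equal
#' to a threshold falls in the higher class), matching CAPRI-style usage.
#'
#' @param acceptable_min,medium_min,high_min class lower bounds.
#' @return a named list of the three thresholds, validated.
#' @export
dockq_thresholds <- function(acceptable_min = 0.23, medium_min = 0.49,
                             high_min = 0.80) {
  stopifnot(0 < acceptable_min, acceptable_min < medium_min,
            medium_min < high_min, high_min < 1)
  list(acceptable_min = acceptable_min, medium_min = medium_min,
       high_min = high_min)
}

#' DockQ score from its quality components
#'
#' DockQ = (fnat + 1/(1 + (iRMSD/1.5)^2) + 1/(1 + (LRMSD/8.5)^2)) / 3.
#' All three arguments are vectorised and recycled.
#'
#' @param fnat fraction of native inter-chain contacts preserved, in \[0, 1\].
#' @param irmsd interface RMSD in Angstrom (>= 0).
#' @param lrmsd ligand RMSD in Angstrom (>= 0).
#' @return DockQ scores in \[0, 1\].
#' @examples
#' dockq_score(1, 0, 0)        # 1.0: perfect model
#' dockq_score(0.5, 1.5, 8.5)  # 0.5: every term at its half-point
#' @export
dockq_score <- function(fnat, irmsd, lrmsd) {
  if (any(fnat < 0 | fnat > 1, na.rm = TRUE)) {
    stop("fnat must lie in [0, 1]", call. = FALSE)
  }
  if (any(irmsd < 0 | lrmsd < 0, na.rm = TRUE)) {
    stop("RMSDs must be non-negative", call. = FALSE)
  }
  (fnat + 1 / (1 + (irmsd / DOCKQ_D1)^2) + 1 / (1 + (lrmsd / DOCKQ_D2)^2)) / 3
}

#' Discretise DockQ scores into the four CAPRI-style quality classes
#'
#' Incorrect below `acceptable_min`, Acceptable up to `medium_min`, Medium up
#' to `high_min`, High at or above `high_min`; lower bounds inclusive.
#'
#' @param score DockQ scores in \[0, 1\] (vectorised).
#' @param thresholds a list from [dockq_thresholds()].
#' @return a factor with levels Incorrect, Acceptable, Medium, High.
#' @export
dockq_class <- function(score, thresholds = dockq_thresholds()) {
  stopifnot(all(score >= 0 & score <= 1, na.rm = TRUE))
  cls <- ifelse(score >= thresholds$high_min, "High",
         ifelse(score >= thresholds$medium_min, "Medium",
         ifelse(score >= thresholds$acceptable_min, "Acceptable",
                "Incorrect")))
  factor(cls, levels = QUALITY_CLASSES)
}

#' Read a decoy label table
#'
#' Accepts CSV/TSV with either a `dockq` column or the three component
#' columns `fnat`, `irmsd`, `lrmsd` (exactly one of the two column sets must
#' be present); component rows are converted through [dockq_score()].  A
#' `decoy_id` column is required; `target_id` is carried through if present.
#'
#' @param path CSV or TSV file.
#' @param thresholds class thresholds for labelling.
#' @return a tibble with columns `decoy_id`, (`target_id`,) `dockq`, `class`.
#' @export
read_dockq_table <- function(path, thresholds = dockq_thresholds()) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          comment = "#")
  names(df) <- tolower(names(df))
  if (!"decoy_id" %in% names(df)) {
    stop("label table needs a decoy_id column", call. = FALSE)
  }
  has_dockq <- "dockq" %in% names(df)
  has_comp <- all(c("fnat", "irmsd", "lrmsd") %in% names(df))
  if (has_dockq == has_comp) {
    stop("label table must have either a dockq column or fnat/irmsd/lrmsd ",
         "columns, not ", if (has_dockq) "both" else "neither", call. = FALSE)
  }
  if (has_comp) {
    bad <- which(is.na(df$fnat) | is.na(df$irmsd) | is.na(df$lrmsd))
    if (length(bad) > 0) {
      stop("malformed component values at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    df$dockq <- dockq_score(df$fnat, df$irmsd, df$lrmsd)
  }
  if (anyNA(df$dockq)) {
    stop("malformed dockq values at data row(s) ",
         paste(which(is.na(df$dockq)), collapse = ", "), call. = FALSE)
  }
  df$class <- dockq_class(df$dockq, thresholds)
  keep <- intersect(c("target_id", "decoy_id", "dockq", "class"), names(df))
  tibble::as_tibble(df[, keep])
}

#' Parse the text report of the reference DockQ tool
#'
#' Extracts the DockQ, Fnat, iRMS and LRMS fields from the free-text output
#' format of the upstream DockQ program, for use as an external label source.
#'
#' @param path text file produced by the DockQ tool.
#' @return a one-row tibble with columns `fnat`, `irmsd`, `lrmsd`, `dockq`.
#' @export
read_dockq_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  tibble::tibble(fnat = grab("Fnat"), irmsd = grab("iRMS"),
                 lrmsd = grab("LRMS"), dockq = grab("DockQ"))
}
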