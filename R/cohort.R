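#' Construct a connectome cohort
#'
#' A cohort bundles, per subject: optional regional time series (T x p),
#' empirical FC, SC (streamline counts and/or Gaussian-resampled weights) and a
#' scalar cognition score — all tied to a single atlas. Components may be
#' supplied directly or filled in later (e.g. SC by [generate_sc()]).
#'
#' @param atlas An `fc_atlas`.
#' @param efc List of p x p FC matrices, one per subject (optional if
#'   `time_series` given, in which case eFC is computed via [compute_efc()]).
#' @param time_series Optional list of T x p matrices.
#' @param sc Optional list of p x p streamline-count matrices.
#' @param sc_resampled Optional list of Gaussian-resampled SC matrices.
#' @param cognition Optional numeric vector, one score per subject.
#' @param ids Subject identifiers (default `sub001`, ...).
#' @param meta Optional list of generator metadata.
#' @return Object of class `fc_cohort`.
#' @export
fc_cohort <- function(atlas, efc = NULL, time_series = NULL, sc = NULL,
                      sc_resampled = NULL, cognition = NULL, ids = NULL,
                      meta = list()) {
  stopifnot(inherits(atlas, "fc_atlas"))
  if (is.null(efc) && is.null(time_series)) {
    stop("supply 'efc' and/or 'time_series'", call. = FALSE)
  }
  n <- length(efc %||% time_series)
  if (n < 1) stop("cohort must contain at least one subject", call. = FALSE)
  if (is.null(efc)) efc <- lapply(time_series, compute_efc)
  p <- atlas$p
  for (m in efc) {
    if (!is_square_matrix(m) || nrow(m) != p) {
      stop("every eFC matrix must be ", p, " x ", p, call. = FALSE)
    }
  }
  check_list_dim <- function(lst, what) {
    if (!is.null(lst)) {
      if (length(lst) != n) stop(what, " must have one entry per subject", call. = FALSE)
      for (m in lst) {
        if (!is_square_matrix(m) || nrow(m) != p) {
          stop("every ", what, " matrix must be ", p, " x ", p, call. = FALSE)
        }
      }
    }
  }
  check_list_dim(sc, "sc")
  check_list_dim(sc_resampled, "sc_resampled")
  if (!is.null(cognition) && length(cognition) != n) {
    stop("'cognition' must have one score per subject", call. = FALSE)
  }
  ids <- ids %||% sprintf("sub%03d", seq_len(n))
  structure(
    list(atlas = atlas, ids = ids, n = n, efc = efc,
         time_series = time_series, sc = sc, sc_resampled = sc_resampled,
         cognition = cognition, meta = meta),
    class = "fc_cohort"
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  have <- c(
    if (!is.null(x$time_series)) "time series",
    "eFC",
    if (!is.null(x$sc)) "SC counts",
    if (!is.null(x$sc_resampled)) "SC resampled",
    if (!is.null(x$cognition)) "cognition"
  )
  cat(sprintf("<fc_cohort> %d subjects, %d parcels; components: %s\n",
              x$n, x$atlas$p, paste(have, collapse = ", ")))
  invisible(x)
}

#' Edge-vector matrix of a cohort component
#'
#' Stacks the canonical edge vectors of one connectivity component into an
#' n_subjects x n_edges matrix — the feature layout used by the MLP and the
#' cognition analyses.
#'
#' @param cohort An `fc_cohort`.
#' @param component One of "efc", "sc", "sc_resampled".
#' @return Numeric matrix, rows = subjects, columns = edges.
#' @export
cohort_edges <- function(cohort, component = c("efc", "sc", "sc_resampled")) {
  component <- match.arg(component)
  lst <- cohort[[component]]
  if (is.null(lst)) stop("cohort has no '", component, "' component", call. = FALSE)
  t(vapply(lst, vectorize, numeric(cohort$atlas$p * (cohort$atlas$p - 1) / 2)))
}

#' Write / read a cohort to a directory
#'
#' Plain-text serialization: a JSON manifest (`manifest.json`) listing subject
#' IDs, file paths, the seed used to generate the data (if any) and the atlas
#' file; per-subject matrices and time series as TSV; cognition as a two-column
#' TSV.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `read_cohort` returns an `fc_cohort`; `write_cohort` the directory,
#'   invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  comp_files <- list()
  for (comp in c("efc", "sc", "sc_resampled", "time_series")) {
    lst <- cohort[[comp]]
    if (is.null(lst)) next
    files <- sprintf("%s_%s.tsv", cohort$ids, comp)
    for (i in seq_along(lst)) {
      if (comp == "time_series") {
        write.table(lst[[i]], file.path(dir, files[i]), sep = "\t",
                    quote = FALSE, row.names = FALSE,
                    col.names = cohort$atlas$labels)
      } else {
        write_conn_tsv(lst[[i]], file.path(dir, files[i]),
                       labels = cohort$atlas$labels)
      }
    }
    comp_files[[comp]] <- files
  }
  if (!is.null(cohort$cognition)) {
    write.table(data.frame(subject = cohort$ids, cognition = cohort$cognition),
                file.path(dir, "cognition.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  manifest <- list(
    subjects = cohort$ids, atlas = "atlas.tsv", files = comp_files,
    cognition = if (!is.null(cohort$cognition)) "cognition.tsv",
    meta = cohort$meta
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  atlas <- read_atlas(file.path(dir, manifest$atlas))
  comps <- list()
  for (comp in names(manifest$files)) {
    files <- manifest$files[[comp]]
    comps[[comp]] <- lapply(files, function(f) {
      m <- as.matrix(read.delim(file.path(dir, f), check.names = FALSE))
      if (comp != "time_series") rownames(m) <- colnames(m)
      m
    })
  }
  cognition <- NULL
  if (!is.null(manifest$cognition)) {
    cog <- read.delim(file.path(dir, manifest$cognition))
    cognition <- cog$cognition[match(manifest$subjects, cog$subject)]
  }
  fc_cohort(atlas,
            efc = comps$efc, time_series = comps$time_series,
            sc = comps$sc, sc_resampled = comps$sc_resampled,
            cognition = cognition, ids = manifest$subjects,
            meta = manifest$meta %||% list())
}
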