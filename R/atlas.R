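#' Yeo 7-network codes
#'
#' Canonical abbreviations for the seven cortical functional systems of Yeo
#' et al.: visual (VN), somatomotor (SMN), dorsal attention (DAN), ventral
#' attention (VAN), limbic (LSN), frontoparietal (FPN) and default mode (DMN).
#'
#' @export
yeo7_networks <- c("VN", "SMN", "DAN", "VAN", "LSN", "FPN", "DMN")

#' Construct a parcellation atlas
#'
#' An atlas is a set of uniquely labelled cortical parcels, each assigned to
#' exactly one of the seven Yeo functional networks. All connectivity matrices
#' in a cohort are indexed by one atlas.
#'
#' @param labels Character vector of unique parcel labels.
#' @param networks Character vector (same length) of Yeo-7 network codes,
#'   each one of [yeo7_networks].
#' @return An object of class `fc_atlas` with fields `p`, `labels`, `networks`.
#' @examples
#' atl <- fc_atlas(c("A", "B", "C"), c("VN", "VN", "DMN"))
#' atl$p
#' @export
fc_atlas <- function(labels, networks) {
  labels <- as.character(labels)
  networks <- as.character(networks)
  if (length(labels) < 2) stop("an atlas needs at least 2 parcels", call. = FALSE)
  if (anyDuplicated(labels)) stop("parcel labels must be unique", call. = FALSE)
  if (length(networks) != length(labels)) {
    stop("'networks' must have one entry per parcel", call. = FALSE)
  }
  bad <- setdiff(unique(networks), yeo7_networks)
  if (length(bad)) {
    stop("unknown network code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(p = length(labels), labels = labels, networks = networks),
    class = "fc_atlas"
  )
}

# Build a preset atlas with given per-network parcel counts.
preset_atlas <- function(prefix, counts) {
  networks <- rep(names(counts), counts)
  labels <- sprintf("%s_%s_%02d", prefix, networks,
                    unlist(lapply(counts, seq_len), use.names = FALSE))
  fc_atlas(labels, networks)
}

#' Preset atlases
#'
#' Two ready-made atlases mirroring the parcellations most used in human
#' connectome work: a 68-parcel anatomical atlas in the style of
#' Desikan-Killiany (`atlas_dk_like`) and a 200-parcel functional atlas in the
#' style of Schaefer (`atlas_schaefer_like`). Parcels are assigned to the Yeo-7
#' networks in roughly realistic proportions; they are synthetic stand-ins, not
#' the published atlas files.
#'
#' @return An `fc_atlas`.
#' @examples
#' atlas_dk_like()$p        # 68
#' atlas_schaefer_like()$p  # 200
#' @export
atlas_dk_like <- function() {
  preset_atlas("DK", c(VN = 9, SMN = 10, DAN = 7, VAN = 7,
                       LSN = 6, FPN = 10, DMN = 19))
}

#' @rdname atlas_dk_like
#' @export
atlas_schaefer_like <- function() {
  preset_atlas("SCH", c(VN = 30, SMN = 34, DAN = 26, VAN = 24,
                        LSN = 12, FPN = 30, DMN = 44))
}

#' @export
print.fc_atlas <- function(x, ...) {
  cat(sprintf("<fc_atlas> %d parcels, Yeo-7 networks\n", x$p))
  print(table(factor(x$networks, levels = yeo7_networks)))
  invisible(x)
}

#' Read / write an atlas as TSV
#'
#' Two-column tab-separated file with header `parcel_label` and `network`.
#'
#' @param atlas An `fc_atlas`.
#' @param path File path.
#' @return `read_atlas` returns an `fc_atlas`; `write_atlas` returns `path`
#'   invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "fc_atlas"))
  df <- data.frame(parcel_label = atlas$labels, network = atlas$networks)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parcel_label", "network") %in% names(df))) {
    stop("atlas file needs columns 'parcel_label' and 'network'", call. = FALSE)
  }
  fc_atlas(df$parcel_label, df$network)
}
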