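## File formats: design TSV + segments FASTA, intensity TSV, KeqTable
## TSV, run configuration (YAML key-value file). All coordinates in
## files are 1-based inclusive; output files carry a provenance header.

.provenanceHeader <- function(what) {
  ver <- tryCatch(as.character(utils::packageVersion("probeForest")),
                  error = function(e) "dev")
  sprintf("# probeForest %s | %s | generated %s", ver, what,
          format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
}

#' Read a chip design from a design TSV and a segments FASTA
#'
#' The design TSV needs columns \code{probe_id}, \code{sequence} (probe,
#' 5'->3'), \code{strand} ("+"/"-"), \code{segment_id}, and optionally
#' \code{replicate_group} and \code{locus}. Sequences are uppercased;
#' non-ACGT characters are rejected. FASTA record names must cover every
#' \code{segment_id}. Lines starting with \code{#} are ignored; CRLF and
#' LF files parse identically.
#'
#' @param designTsv path to the design table.
#' @param segmentsFasta path to the segments FASTA.
#' @param strict error (instead of warn) on ragged probe lengths.
#' @return a \linkS4class{ChipDesign}.
#' @export
readDesign <- function(designTsv, segmentsFasta, strict = FALSE) {
  tab <- utils::read.delim(designTsv, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "sequence", "strand", "segment_id")
  if (!all(need %in% names(tab)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("design table is empty")
  tab$sequence <- toupper(tab$sequence)
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe_id: ",
         tab$probe_id[duplicated(tab$probe_id)][1L])
  if (!"replicate_group" %in% names(tab))
    tab$replicate_group <- NA_character_
  if (!"locus" %in% names(tab)) tab$locus <- NA_character_
  ## all-NA optional columns come back logical from read.delim
  tab$replicate_group <- as.character(tab$replicate_group)
  tab$locus <- as.character(tab$locus)
  segs <- Biostrings::readDNAStringSet(segmentsFasta)
  names(segs) <- sub("\\s.*$", "", names(segs))
  miss <- setdiff(unique(tab$segment_id), names(segs))
  if (length(miss))
    stop("probe(s) reference segment_id missing from FASTA: ",
         paste(miss, collapse = ", "),
         " (probes e.g. ",
         tab$probe_id[match(miss[1L], tab$segment_id)], ")")
  if (length(unique(nchar(tab$sequence))) > 1L) {
    msg <- "ragged probe lengths in design"
    if (strict) stop(msg) else warning(msg)
  }
  new("ChipDesign", probes = tab[c("probe_id", "sequence", "strand",
                                   "segment_id", "replicate_group",
                                   "locus")],
      segments = segs)
}

#' Write a chip design to a design TSV and segments FASTA
#'
#' @param design a \linkS4class{ChipDesign}.
#' @param designTsv,segmentsFasta output paths.
#' @return invisibly, the design.
#' @export
writeDesign <- function(design, designTsv, segmentsFasta) {
  con <- file(designTsv, "w")
  writeLines(.provenanceHeader("chip design"), con)
  utils::write.table(design@probes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  Biostrings::writeXStringSet(design@segments, segmentsFasta)
  invisible(design)
}

#' Read observed probe intensities
#'
#' TSV with columns \code{probe_id} and \code{intensity}; intensities
#' must be >= 0 or NA (NA rows are preserved as missing and counted in
#' \code{\link{pfDiagnostics}}); scientific notation is accepted.
#'
#' @param tsv path.
#' @return named numeric vector (names = probe_id; NAs kept).
#' @export
readIntensities <- function(tsv) {
  tab <- utils::read.delim(tsv, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(probe_id = "character",
                                          intensity = "numeric"))
  if (!all(c("probe_id", "intensity") %in% names(tab)))
    stop("intensity table must have columns probe_id, intensity")
  if (nrow(tab) == 0L) stop("intensity table is empty")
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe_id: ",
         tab$probe_id[duplicated(tab$probe_id)][1L])
  if (any(tab$intensity < 0, na.rm = TRUE))
    stop("negative intensity for probe ",
         tab$probe_id[which(tab$intensity < 0)[1L]])
  nmiss <- sum(is.na(tab$intensity))
  if (nmiss) .diagBump("missing_intensities_read", nmiss)
  stats::setNames(tab$intensity, tab$probe_id)
}

#' Write probe intensities
#'
#' @param intensities named numeric vector or data.frame(probe_id,
#'   intensity).
#' @param tsv output path.
#' @return invisibly, the path.
#' @export
writeIntensities <- function(intensities, tsv) {
  if (!is.data.frame(intensities))
    intensities <- data.frame(probe_id = names(intensities),
                              intensity = as.numeric(intensities))
  con <- file(tsv, "w")
  writeLines(.provenanceHeader("probe intensities"), con)
  utils::write.table(intensities, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(tsv)
}

#' Write an equilibrium-constant table
#'
#' @param table a \linkS4class{KeqTable}.
#' @param tsv output path.
#' @return invisibly, the path.
#' @export
writeKeqTable <- function(table, tsv) {
  con <- file(tsv, "w")
  writeLines(.provenanceHeader(
    sprintf("KeqTable probe_variant=%s tempK=%g na=%g",
            table@probeVariantId, table@tempK, table@na)), con)
  e <- table@entries
  e <- cbind(probe_variant_id = table@probeVariantId, e)
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(tsv)
}

#' Read a run configuration file
#'
#' YAML key-value file with defaults mirroring the standard protocol:
#' temperature 42 C, 1 M Na+, scanner 100/65536/7, single fragmentation
#' and wash values (or grids for fitting). Unknown keys are rejected;
#' invalid values get actionable messages.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return validated named list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- list(temperature_c = 42, na_molar = 1,
              scanner = list(min = 100, max = 65536, gomp = 7),
              mean_fragment_size = 50, wash_keq_threshold = 0,
              prune = 1e-12, seed = 1,
              fit = list(n_restarts = 2, tolerance = 1e-9,
                         max_iterations = 40, objective_scale = "raw"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           "; known keys: ", paste(names(cfg), collapse = ", "))
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(bad))
          stop("unknown config key(s) under ", k, ": ",
               paste(bad, collapse = ", "))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else cfg[[k]] <- user[[k]]
    }
  }
  if (cfg$temperature_c <= -273.15)
    stop("temperature_c must be above absolute zero")
  if (cfg$na_molar <= 0) stop("na_molar must be > 0")
  if (!(cfg$scanner$min > 0 && cfg$scanner$max > cfg$scanner$min))
    stop("scanner settings need 0 < min < max")
  if (cfg$scanner$gomp <= 0) stop("scanner gomp must be > 0")
  if (any(cfg$mean_fragment_size < 1))
    stop("mean_fragment_size values must be >= 1")
  if (any(cfg$wash_keq_threshold < 0))
    stop("wash_keq_threshold values must be >= 0")
  cfg
}
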