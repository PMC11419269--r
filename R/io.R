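#' Read protein sequences from FASTA
#'
#' Standard multi-record FASTA via Biostrings; identifiers are the first
#' whitespace-delimited word of each header. Sequences are uppercased and
#' must contain only the 20 standard residues -- gaps, ambiguity codes and
#' duplicated identifiers are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  ok <- "^[ARNDCQEGHILKMFPSTWYV]+$"
  bad <- which(!grepl(ok, seqs))
  if (length(bad)) {
    res <- strsplit(seqs[bad[1L]], "")[[1L]]
    p <- which(!res %in% strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]])[1L]
    stop(sprintf("record '%s': non-standard character '%s' at position %d",
                 ids[bad[1L]], res[p], p))
  }
  seqs
}

#' Path to a bundled data file
#'
#' Convenience accessor for the package's packaged inputs: the human TREM2
#' and IL-34 precursor FASTA files and the variant panel table.
#'
#' @param file File name under `extdata`; with no argument, lists what is
#'   available.
#' @return File path (or vector of available names).
#' @examples
#' trem2map_extdata()
#' @export
trem2map_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "trem2map", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled file '", file, "'")
  path
}

#' Write sensorgrams to CSV
#'
#' Long-format CSV with columns `time_s`, `signal_nm`, `phase`, `conc_M`,
#' `sensor_id`. Generator parameters, seed and any metadata scalars are
#' written as `# key=value` header comments so that the file suffices to
#' regenerate the traces.
#'
#' @param sensorgrams A `sensorgram` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(sensorgrams, path) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  meta <- attr(sensorgrams[[1L]], "meta")
  hdr <- character()
  if (!is.null(meta$params))
    hdr <- c(hdr, sprintf("# kon=%.8g koff=%.8g Rmax=%.8g",
                          meta$params$kon, meta$params$koff,
                          meta$params$Rmax))
  for (k in c("noise_sd", "drift_slope", "seed"))
    if (!is.null(meta[[k]]))
      hdr <- c(hdr, sprintf("# %s=%.8g", k, meta[[k]]))
  rows <- do.call(rbind, lapply(sensorgrams, function(sg)
    data.frame(time_s = sg$time, signal_nm = sg$signal, phase = sg$phase,
               conc_M = attr(sg, "analyte_conc"),
               sensor_id = attr(sg, "sensor_id"),
               stringsAsFactors = FALSE)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sensorgrams written by [write_sensorgram_csv()]
#'
#' @param path CSV file.
#' @return List of `sensorgram`s, one per sensor, in file order.
#' @export
read_sensorgram_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "signal_nm", "phase", "conc_M", "sensor_id")
  if (!all(need %in% names(df)))
    stop("not a sensorgram CSV (missing columns)")
  lapply(split(df, factor(df$sensor_id, unique(df$sensor_id))), function(d)
    new_sensorgram(d$time_s, d$signal_nm, d$phase, d$conc_M[1L],
                   d$sensor_id[1L]))
}

#' Write a screen hit or region table as TSV
#'
#' Stable column order, floats at fixed precision, list columns (the
#' per-residue hit counts) serialized as comma-joined integers. The
#' resolved configuration can be recorded as `# key=value` comments.
#'
#' @param x data.frame (screen hits, clustered regions, fit report...).
#' @param path Output file.
#' @param config Optional named list echoed into header comments.
#' @param digits Decimal digits for numeric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path, config = NULL, digits = 4L) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]]))
      x[[j]] <- vapply(x[[j]], paste, "", collapse = ",")
    else if (is.numeric(x[[j]]) && !is.integer(x[[j]]))
      x[[j]] <- formatC(x[[j]], digits = digits, format = "f")
  }
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# %s=%s", names(config),
                       vapply(config, format, "")), con)
  utils::write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export clustered regions as BED
#'
#' Opt-in alternative to the default 1-based inclusive precursor
#' coordinates: BED uses 0-based half-open intervals.
#'
#' @param regions Region table from [cluster_hits()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$sequence_id,
                    chromStart = regions$start - 1L,
                    chromEnd = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    score = regions$supporting_hits)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fetch a UniProt sequence by accession (network-gated)
#'
#' Retrieval is disabled unless `allow_network = TRUE`; offline use should
#' supply sequences as FASTA (see [read_fasta()] and the bundled files in
#' [trem2map_extdata()]). Fetched sequences are cached as FASTA with the
#' accession and retrieval date, and cached copies are served without any
#' network access.
#'
#' @param accession UniProt accession (validated before any network use).
#' @param cache_dir Directory for cached FASTA files.
#' @param allow_network Explicit opt-in for the download.
#' @return Named character vector of length 1.
#' @export
fetch_accession <- function(accession,
                            cache_dir = tools::R_user_dir("trem2map",
                                                          "cache"),
                            allow_network = FALSE) {
  if (!grepl("^[A-NR-Z][0-9][A-Z0-9]{3}[0-9]$|^[OPQ][0-9][A-Z0-9]{3}[0-9]$",
             accession))
    stop("malformed UniProt accession: '", accession, "'")
  cached <- file.path(cache_dir, paste0(accession, ".fasta"))
  if (file.exists(cached)) return(read_fasta(cached))
  if (!allow_network)
    stop("network retrieval disabled; supply the sequence as FASTA ",
         "(read_fasta) or call with allow_network = TRUE",
         call. = FALSE)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accession)
  utils::download.file(url, cached, quiet = TRUE)
  writeLines(sprintf("%s retrieved %s", accession, format(Sys.Date())),
             file.path(cache_dir, paste0(accession, ".date")))
  read_fasta(cached)
}
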