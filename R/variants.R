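#' Parse a slash-delimited variant name
#'
#' Variant names follow the convention used throughout the TREM2 mutant
#' panel: one or more tokens `X<position>Y` joined by `/`, e.g.
#' `"W44D/L69D/L71D"`. The special name `"WT"` denotes the wild-type
#' (empty mutation list).
#'
#' @param name Variant name string.
#' @param site_map Position-to-site map used to classify the variant, see
#'   [trem2_site_map()].
#' @return `trem2_variant` object: list with `name`, `mutations`
#'   (data.frame `wt`, `pos`, `mut`, ascending by position) and
#'   `site_class`.
#' @examples
#' parse_variant("R47H")
#' parse_variant("W44D/L69D/L71D")$mutations
#' @export
parse_variant <- function(name, site_map = trem2_site_map()) {
  if (length(name) != 1L || !is.character(name) || !nzchar(name))
    stop("'name' must be a single non-empty string")
  if (toupper(name) == "WT") {
    mut <- data.frame(wt = character(), pos = integer(), mut = character())
    return(structure(list(name = "WT", mutations = mut, site_class = "WT"),
                     class = "trem2_variant"))
  }
  tokens <- strsplit(name, "/", fixed = TRUE)[[1L]]
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad))
    stop(sprintf("malformed mutation token '%s' in '%s'", tokens[bad[1L]], name))
  mut <- data.frame(
    wt  = toupper(vapply(m, `[`, "", 2L)),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    mut = toupper(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (any(mut$wt == mut$mut))
    stop("wild-type and mutant residue identical in '", name, "'")
  if (anyDuplicated(mut$pos))
    stop("duplicate mutated position in '", name, "'")
  mut <- mut[order(mut$pos), , drop = FALSE]
  rownames(mut) <- NULL
  structure(list(name = format_variant_name(mut), mutations = mut,
                 site_class = classify_site(mut$pos, site_map)),
            class = "trem2_variant")
}

format_variant_name <- function(mutations) {
  if (nrow(mutations) == 0L) return("WT")
  paste(sprintf("%s%d%s", mutations$wt, mutations$pos, mutations$mut),
        collapse = "/")
}

#' @export
format.trem2_variant <- function(x, ...) x$name

#' @export
print.trem2_variant <- function(x, ...) {
  cat(sprintf("<trem2_variant> %s (%d mutation%s, site: %s)\n", x$name,
              nrow(x$mutations), if (nrow(x$mutations) == 1L) "" else "s",
              x$site_class))
  invisible(x)
}

#' Apply a variant's mutations to a sequence
#'
#' The wild-type residue of every mutation is checked against the sequence
#' before substitution; a mismatch aborts with the position and the residue
#' actually observed, which guards against numbering-offset mistakes.
#'
#' @param sequence Residue string in precursor numbering (position 1 =
#'   first residue of `sequence`).
#' @param variant `trem2_variant` or a variant name string.
#' @return Mutated residue string.
#' @examples
#' apply_mutations("MARA", "R3K")
#' @export
apply_mutations <- function(sequence, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  stopifnot(inherits(variant, "trem2_variant"))
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- variant$mutations
  if (nrow(m) == 0L) return(sequence)
  if (any(m$pos > length(res)))
    stop("mutation position beyond sequence length")
  obs <- res[m$pos]
  off <- which(obs != m$wt)
  if (length(off))
    stop(sprintf("wild-type mismatch at position %d: expected %s, found %s",
                 m$pos[off[1L]], m$wt[off[1L]], obs[off[1L]]))
  res[m$pos] <- m$mut
  paste(res, collapse = "")
}

#' TREM2 binding-site position map
#'
#' Positions of the mutated residues grouped by the binding surface they
#' probe: the hydrophobic site (CDR-loop patch), the basic site, residues
#' adjacent to the basic site, and site 2. AD-risk positions are listed
#' separately; two of them (47, 62) lie in the basic site, which takes
#' precedence for classification.
#'
#' @return Named list of integer position vectors.
#' @export
trem2_site_map <- function() {
  list(hydrophobic = c(41L, 44L, 69L, 70L, 71L, 74L, 89L),
       basic = c(46L, 47L, 62L, 76L, 77L, 78L),
       `basic-adjacent` = c(75L, 85L),
       site2 = c(122L, 123L),
       `AD-risk` = c(47L, 62L, 87L, 96L))
}

#' Classify mutated positions by TREM2 binding site
#'
#' Each position is assigned to the hydrophobic, basic, basic-adjacent or
#' site-2 surface; positions carrying only an AD-risk annotation (87, 96)
#' classify as `"AD-risk"`. A set of positions spanning more than one class
#' is `"mixed"`; positions in no configured site classify `"unassigned"`
#' with a warning.
#'
#' @param positions Integer vector of precursor positions.
#' @param site_map See [trem2_site_map()].
#' @return Single class string.
#' @examples
#' classify_site(c(69, 71))   # hydrophobic
#' classify_site(c(46, 69))   # mixed
#' @export
classify_site <- function(positions, site_map = trem2_site_map()) {
  if (length(positions) == 0L) return("WT")
  prim <- setdiff(names(site_map), "AD-risk")
  cls <- vapply(positions, function(p) {
    hit <- prim[vapply(prim, function(s) p %in% site_map[[s]], logical(1))]
    if (length(hit)) return(hit[1L])
    if (p %in% site_map[["AD-risk"]]) return("AD-risk")
    "unassigned"
  }, character(1))
  if (any(cls == "unassigned"))
    warning("position(s) ", paste(positions[cls == "unassigned"],
                                  collapse = ", "),
            " not in any configured binding site")
  u <- unique(cls)
  if (length(u) == 1L) u else "mixed"
}

parse_kd_column <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  note <- ifelse(is.na(num) & nzchar(x) & x != "-", x, "")
  list(kd = num, note = note)
}

#' The TREM2 variant panel with per-ligand affinities
#'
#' Reads the packaged variant table: every variant named in the mutant
#' panel's binding studies, its binding-site class and provenance, and the
#' reported dissociation constants for apoE4 (nM), C1q (uM) and IL-34 (nM)
#' with their standard errors. Qualitative entries ("No Binding",
#' "N.B.D.", "Decreased binding", "Binding (not fit)") are preserved in
#' `*_note` columns and give `NA` in the numeric columns; [fold_change()]
#' refuses them rather than producing NaN.
#'
#' @return data.frame, one row per variant.
#' @export
trem2_variant_table <- function() {
  path <- system.file("extdata", "trem2_variants.tsv", package = "trem2map",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  out <- data.frame(variant = raw$variant, site_class = raw$site_class,
                    provenance = raw$provenance, stringsAsFactors = FALSE)
  for (lig in c("apoe4", "c1q", "il34")) {
    kd <- parse_kd_column(raw[[paste0("kd_", lig)]])
    out[[paste0("kd_", lig)]] <- kd$kd
    out[[paste0("kd_", lig, "_se")]] <-
      suppressWarnings(as.numeric(raw[[paste0("kd_", lig, "_se")]]))
    out[[paste0("kd_", lig, "_note")]] <- kd$note
  }
  out$fold_apoe4_printed <- raw$fold_apoe4_printed
  out$fold_il34_printed <- raw$fold_il34_printed
  out
}
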