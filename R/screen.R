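#' Define a sequence motif by precursor coordinates
#'
#' @param name Motif name (e.g. `"CDR2"`, `"Helix 5"`).
#' @param parent_id Identifier of the sequence the motif comes from.
#' @param start,end 1-based inclusive precursor coordinates; length >= 2.
#' @return `motif_def` object.
#' @export
motif_def <- function(name, parent_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("motif requires start <= end")
  if (end - start + 1L < 2L) stop("motif length must be >= 2")
  structure(list(name = name, parent_id = parent_id,
                 start = start, end = end),
            class = "motif_def")
}

#' Screen a motif against a target hydropathy map
#'
#' Slides the motif's binary hydrophobicity map along the target in single
#' residue steps, in forward and (by default) reverse orientation -- the
#' reverse orientation reverses the motif's residue order, modelling
#' antiparallel backbone pairing. Every alignment offset is scored with
#' [percent_match()] and [complementarity()]; a hit is "good" when percent
#' match strictly exceeds `pm_threshold` and complementarity strictly
#' exceeds `c_threshold`.
#'
#' @param motif A `motif_def` plus its `parent` profile, or directly a
#'   `hydropathy_profile` to be used whole as the motif.
#' @param target `hydropathy_profile` to scan.
#' @param parent Profile containing the motif's parent sequence (required
#'   when `motif` is a `motif_def`).
#' @param pm_threshold,c_threshold Strict lower bounds for a good hit
#'   (defaults 75 percent and 0.5).
#' @param orientations Subset of `c("forward", "reverse")`.
#' @return data.frame of class `screen_hits` with one row per offset and
#'   orientation: `motif`, `orientation`, `target_id`, `target_start`,
#'   `target_end`, `percent_match`, `complementarity`, `is_good`.
#' @export
screen_motif <- function(motif, target, parent = NULL, pm_threshold = 75,
                         c_threshold = 0.5,
                         orientations = c("forward", "reverse")) {
  if (inherits(motif, "motif_def")) {
    if (is.null(parent)) stop("'parent' profile required for a motif_def")
    mp <- profile_window(parent, motif$start, motif$end)
    mname <- motif$name
  } else if (inherits(motif, "hydropathy_profile")) {
    mp <- motif
    mname <- motif$sequence_id
  } else stop("'motif' must be a motif_def or hydropathy_profile")
  if (!inherits(target, "hydropathy_profile"))
    stop("'target' must be a hydropathy_profile")
  orientations <- match.arg(orientations, several.ok = TRUE)
  L <- length(mp$residues)
  N <- length(target$residues)
  if (L > N) stop("motif longer than target")
  n_off <- N - L + 1L
  out <- vector("list", length(orientations))
  for (k in seq_along(orientations)) {
    ori <- orientations[k]
    h <- if (ori == "reverse") rev(mp$indices) else mp$indices
    s <- if (ori == "reverse") rev(mp$signs) else mp$signs
    pm <- numeric(n_off); cc <- numeric(n_off)
    for (o in seq_len(n_off)) {
      w <- o:(o + L - 1L)
      pm[o] <- 100 * sum(s != target$signs[w]) / L
      cc[o] <- sum(abs(h - target$indices[w])) / (L * 9)
    }
    out[[k]] <- data.frame(
      motif = mname, orientation = ori,
      target_id = target$sequence_id,
      target_start = target$offset + seq_len(n_off) - 1L,
      target_end = target$offset + seq_len(n_off) + L - 2L,
      percent_match = pm, complementarity = cc,
      is_good = pm > pm_threshold & cc > c_threshold,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  class(hits) <- c("screen_hits", "data.frame")
  hits
}

#' Cluster good screen hits into candidate binding regions
#'
#' Takes the union of hit spans on the target sequence, merging spans
#' separated by at most `gap_tolerance` unhit residues, and reports the
#' number of supporting hits and per-residue hit counts (how many good
#' hits cover each residue of a region).
#'
#' @param hits `screen_hits` data.frame (rows with `is_good == FALSE` are
#'   dropped), or any data.frame with `target_start`/`target_end`.
#' @param gap_tolerance Maximum number of unhit residues bridged when
#'   merging adjacent spans (default 3).
#' @param min_hits Minimum number of supporting good hits a region needs to
#'   be reported (default 1 = the pure interval union).
#' @return data.frame with `sequence_id`, `start`, `end`,
#'   `supporting_hits`, and a list column `per_residue_hit_counts`.
#'   Empty input gives a zero-row frame.
#' @export
cluster_hits <- function(hits, gap_tolerance = 3L, min_hits = 1L) {
  if (gap_tolerance < 0) stop("'gap_tolerance' must be >= 0")
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), supporting_hits = integer())
  empty$per_residue_hit_counts <- list()
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if ("is_good" %in% names(hits)) hits <- hits[hits$is_good, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  sid <- if ("target_id" %in% names(hits)) unique(hits$target_id) else "seq"
  if (length(sid) != 1L) stop("hits must all reference one target sequence")
  o <- order(hits$target_start, hits$target_end)
  st <- hits$target_start[o]; en <- hits$target_end[o]
  reg_start <- st[1L]; reg_end <- en[1L]
  starts <- integer(); ends <- integer(); nhit <- integer()
  members <- list(); cur <- 1L
  if (nrow(hits) > 1L) {
    for (i in 2L:length(st)) {
      if (st[i] - reg_end - 1L <= gap_tolerance) {
        reg_end <- max(reg_end, en[i]); cur <- c(cur, i)
      } else {
        starts <- c(starts, reg_start); ends <- c(ends, reg_end)
        nhit <- c(nhit, length(cur)); members <- c(members, list(cur))
        reg_start <- st[i]; reg_end <- en[i]; cur <- i
      }
    }
  }
  starts <- c(starts, reg_start); ends <- c(ends, reg_end)
  nhit <- c(nhit, length(cur)); members <- c(members, list(cur))
  counts <- lapply(seq_along(starts), function(r) {
    pos <- starts[r]:ends[r]
    vapply(pos, function(p)
      sum(st[members[[r]]] <= p & en[members[[r]]] >= p), integer(1))
  })
  out <- data.frame(sequence_id = sid, start = starts, end = ends,
                    supporting_hits = nhit, stringsAsFactors = FALSE)
  out$per_residue_hit_counts <- counts
  out <- out[out$supporting_hits >= min_hits, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Default TREM2 screening segments
#'
#' The three CDR loops forming the hydrophobic site and the four strands
#' forming the basic site of the TREM2 Ig domain, in precursor numbering.
#'
#' @return data.frame with `name`, `start`, `end`, `site`.
#' @export
trem2_segments <- function() {
  data.frame(
    name  = c("CDR1", "CDR2", "CDR3",
              "Basic strand 1", "Basic strand 2", "Basic strand 3",
              "Basic strand 4"),
    start = c(39L, 69L, 88L, 47L, 62L, 76L, 112L),
    end   = c(46L, 75L, 91L, 50L, 68L, 78L, 114L),
    site  = c("hydrophobic", "hydrophobic", "hydrophobic",
              "basic", "basic", "basic", "basic"),
    stringsAsFactors = FALSE)
}

#' Default IL-34 helix segments
#'
#' Spans of the six helices of the IL-34 helical bundle in precursor
#' numbering; helices 2-6 follow the annotated helix regions of the mature
#' cytokine, helix 1 is the N-terminal helix after the signal peptide.
#' Spans are configuration, not hard-coded into the screen.
#'
#' @return data.frame with `name`, `start`, `end`.
#' @export
il34_helices <- function() {
  data.frame(
    name  = paste("Helix", 1:6),
    start = c(35L, 71L, 90L, 119L, 142L, 156L),
    end   = c(53L, 85L, 100L, 129L, 151L, 179L),
    stringsAsFactors = FALSE)
}

screen_segments <- function(segments, parent, target, pm_threshold,
                            c_threshold) {
  hits <- lapply(seq_len(nrow(segments)), function(i) {
    screen_motif(motif_def(segments$name[i], parent$sequence_id,
                           segments$start[i], segments$end[i]),
                 target, parent = parent, pm_threshold = pm_threshold,
                 c_threshold = c_threshold)
  })
  hits <- do.call(rbind, hits)
  class(hits) <- c("screen_hits", "data.frame")
  hits
}

#' Bidirectional TREM2/IL-34 hydropathy-complementarity screen
#'
#' Runs the full two-way screen used to predict the TREM2/IL-34 binding
#' interface from sequence alone: the six IL-34 helices are screened against
#' the TREM2 Ig domain (precursor residues 18-130), and the TREM2 CDR loops
#' and basic-site strands are screened against the mature IL-34 sequence
#' (residue 21 to the C-terminus, excluding the signal peptide). Good hits
#' in each direction are clustered into candidate binding regions with
#' [cluster_hits()].
#'
#' @param trem2_seq,il34_seq Full precursor sequences (residue strings).
#' @param scale Hydropathy scale.
#' @param pm_threshold,c_threshold Good-hit thresholds (75, 0.5).
#' @param gap_tolerance Cluster gap tolerance in residues (default 3).
#' @param min_hits Minimum supporting good hits per reported region
#'   (default 2: an isolated single alignment is not treated as a cluster).
#' @param trem2_motifs,il34_motifs Segment tables (`name`, `start`, `end`);
#'   defaults [trem2_segments()] and [il34_helices()].
#' @param trem2_ig TREM2 target range screened by the IL-34 helices.
#' @param il34_mature_start First IL-34 residue screened by TREM2 motifs.
#' @return List with `trem2_regions`, `il34_regions` (clustered region
#'   tables), `trem2_hits`, `il34_hits` (all scored offsets), and
#'   `motif_hit_table` (good-hit counts per motif and orientation).
#' @export
run_binding_site_screen <- function(trem2_seq, il34_seq,
                                    scale = kd_hydropathy(),
                                    pm_threshold = 75, c_threshold = 0.5,
                                    gap_tolerance = 3L, min_hits = 2L,
                                    trem2_motifs = trem2_segments(),
                                    il34_motifs = il34_helices(),
                                    trem2_ig = c(18L, 130L),
                                    il34_mature_start = 21L) {
  trem2 <- hydropathy_profile(trem2_seq, id = "TREM2", scale = scale)
  il34 <- hydropathy_profile(il34_seq, id = "IL34", scale = scale)
  trem2_target <- profile_window(trem2, trem2_ig[1L], trem2_ig[2L])
  il34_target <- profile_window(il34, il34_mature_start,
                                il34$offset + length(il34$residues) - 1L)
  # direction 1: IL-34 helices -> TREM2 Ig domain
  hits_on_trem2 <- screen_segments(il34_motifs, il34, trem2_target,
                                   pm_threshold, c_threshold)
  # direction 2: TREM2 CDR loops + basic strands -> mature IL-34
  hits_on_il34 <- screen_segments(trem2_motifs, trem2, il34_target,
                                  pm_threshold, c_threshold)
  all_hits <- rbind(hits_on_trem2, hits_on_il34)
  good <- all_hits[all_hits$is_good, , drop = FALSE]
  tab <- as.data.frame(table(motif = good$motif,
                             orientation = good$orientation),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "good_hits"
  list(trem2_regions = cluster_hits(hits_on_trem2, gap_tolerance, min_hits),
       il34_regions = cluster_hits(hits_on_il34, gap_tolerance, min_hits),
       trem2_hits = hits_on_trem2, il34_hits = hits_on_il34,
       motif_hit_table = tab)
}
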