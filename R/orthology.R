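blast_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

check_hits <- function(hits) {
  if (!is.data.frame(hits) || !all(blast_columns %in% names(hits)))
    stop("hit table must contain the 12 BLAST tabular columns: ",
         paste(blast_columns, collapse = ", "))
  if (any(hits$evalue < 0)) stop("negative E-values in hit table")
  invisible(hits)
}

#' Filter protein hits by E-value
#'
#' Retains hits at or below the E-value cutoff (default 1e-7), preserving
#' input order.
#'
#' @param hits BLAST tabular hit table (12 columns).
#' @param evalue_cutoff Positive cutoff; hits with `evalue <= cutoff` pass.
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-7) {
  check_hits(hits)
  if (!is.numeric(evalue_cutoff) || evalue_cutoff <= 0)
    stop("'evalue_cutoff' must be positive")
  hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
}

# Attach alignment_rate = aligned length / query protein length.
add_alignment_rate <- function(hits, query_lengths = NULL) {
  if (is.null(query_lengths)) {
    hits$alignment_rate <- NA_real_
    return(hits)
  }
  ql <- stats::setNames(query_lengths$length, query_lengths$gene)
  r <- hits$length / ql[hits$qseqid]
  hits$alignment_rate <- pmin(r, 1)
  hits
}

# Best hit per query under the lexicographic ranking (bit score desc,
# alignment rate desc, identity desc). Queries whose top two hits tie on
# all three keys are dropped entirely (reported by message).
best_hits <- function(hits) {
  if (!nrow(hits))
    return(data.frame(qseqid = character(0), sseqid = character(0)))
  rate <- ifelse(is.na(hits$alignment_rate), -Inf, hits$alignment_rate)
  o <- order(hits$qseqid, -hits$bitscore, -rate, -hits$pident)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  top <- h[first, , drop = FALSE]
  # detect unresolved ties: second-ranked row identical on all three keys
  second_idx <- which(first) + 1L
  ok <- second_idx > nrow(h) | h$qseqid[pmin(second_idx, nrow(h))] != top$qseqid
  tied <- !ok &
    h$bitscore[pmin(second_idx, nrow(h))] == top$bitscore &
    ifelse(is.na(h$alignment_rate[pmin(second_idx, nrow(h))]) &
             is.na(top$alignment_rate), TRUE,
           h$alignment_rate[pmin(second_idx, nrow(h))] == top$alignment_rate) &
    h$pident[pmin(second_idx, nrow(h))] == top$pident
  tied[is.na(tied)] <- FALSE
  if (any(tied))
    message(sum(tied), " quer(ies) dropped: best hit tied on bit score, ",
            "alignment rate and identity")
  top[!tied, c("qseqid", "sseqid"), drop = FALSE]
}

#' Reciprocal best hit orthologue pairs
#'
#' A pair `(a, b)` is returned iff `b` is `a`'s best hit in the A-to-B
#' table and `a` is `b`'s best hit in the B-to-A table.  "Best" is
#' lexicographic on bit score (descending), alignment rate (descending,
#' available when query protein lengths are supplied) and percent identity
#' (descending); queries with an unresolved tie are dropped and reported.
#'
#' @param hits_ab,hits_ba Hit tables in the two directions, already
#'   E-value filtered with [filter_hits()].
#' @param lengths_a,lengths_b Optional query protein length tables
#'   (columns `gene`, `length`) for the two species.
#' @return Data frame with columns `a`, `b`; a one-to-one mapping.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 lengths_a = NULL, lengths_b = NULL) {
  check_hits(hits_ab); check_hits(hits_ba)
  ab <- best_hits(add_alignment_rate(hits_ab, lengths_a))
  ba <- best_hits(add_alignment_rate(hits_ba, lengths_b))
  back <- stats::setNames(ba$sseqid, ba$qseqid)
  keep <- !is.na(back[ab$sseqid]) & back[ab$sseqid] == ab$qseqid
  out <- data.frame(a = ab$qseqid[keep], b = ab$sseqid[keep],
                    row.names = NULL)
  out[order(out$a), , drop = FALSE]
}

check_coords <- function(coords) {
  need <- c("gene", "chrom", "start", "end")
  if (!is.data.frame(coords) || !all(need %in% names(coords)))
    stop("coordinate table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(coords$gene)) stop("duplicate gene ids in coordinates")
  invisible(coords)
}

# Nearest-first neighbour gene ids on each side, same chromosome only.
neighbour_table <- function(coords, flank_window) {
  coords <- coords[order(coords$chrom, coords$start), , drop = FALSE]
  up <- list(); down <- list()
  for (chr in unique(coords$chrom)) {
    g <- coords$gene[coords$chrom == chr]
    for (i in seq_along(g)) {
      up[[g[i]]] <- rev(g[max(1L, i - flank_window):i])[-1L]
      down[[g[i]]] <- g[i:min(length(g), i + flank_window)][-1L]
    }
  }
  list(up = up, down = down)
}

#' Synteny filter on reciprocal-best-hit pairs
#'
#' Keeps a pair `(a, b)` only if the RBH partners of `a`'s flanking genes
#' equal the corresponding flanking genes of `b`.  The comparison is
#' orientation-agnostic: `b`'s neighbours may match in reversed order
#' (local inversion).  Under the default `"strict"` end policy a pair is
#' dropped (and reported) when either gene lacks a full flank window on
#' either side, favouring precision; `"permissive"` evaluates only the
#' sides that exist, truncated to the shorter flank.
#'
#' @param pairs RBH pairs (columns `a`, `b`) from
#'   [reciprocal_best_hits()]; the pair list itself supplies the partner
#'   map used to translate flanking genes.
#' @param coords_a,coords_b Coordinate tables (gene, chrom, start, end).
#' @param flank_window Number of flanking genes per side (default 1).
#' @param end_policy `"strict"` or `"permissive"`, see Details.
#' @return The retained subset of `pairs`.
#' @export
synteny_filter <- function(pairs, coords_a, coords_b, flank_window = 1L,
                           end_policy = c("strict", "permissive")) {
  end_policy <- match.arg(end_policy)
  check_coords(coords_a); check_coords(coords_b)
  if (!nrow(pairs)) return(pairs)
  absent <- !(pairs$a %in% coords_a$gene) | !(pairs$b %in% coords_b$gene)
  if (any(absent))
    message(sum(absent), " pair(s) dropped: gene absent from coordinates")
  pairs <- pairs[!absent, , drop = FALSE]
  na <- neighbour_table(coords_a, flank_window)
  nb <- neighbour_table(coords_b, flank_window)
  partner <- stats::setNames(pairs$b, pairs$a)

  side_ok <- function(ga, gb) {   # nearest-first lists
    if (end_policy == "strict" &&
        (length(ga) < flank_window || length(gb) < flank_window))
      return(NA)                  # unevaluable flank
    m <- min(length(ga), length(gb))
    # both at a scaffold end: vacuous match; only one flankless: mismatch
    if (m == 0L) return(length(ga) == length(gb))
    p <- partner[ga[seq_len(m)]]
    all(!is.na(p) & p == gb[seq_len(m)])
  }

  keep <- logical(nrow(pairs))
  unevaluable <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    same <- c(side_ok(na$up[[a]], nb$up[[b]]),
              side_ok(na$down[[a]], nb$down[[b]]))
    flip <- c(side_ok(na$up[[a]], nb$down[[b]]),
              side_ok(na$down[[a]], nb$up[[b]]))
    if (anyNA(c(same, flip)) && !isTRUE(all(same)) && !isTRUE(all(flip))) {
      unevaluable <- unevaluable + 1L
      keep[i] <- FALSE
    } else {
      keep[i] <- all(same) || all(flip)
    }
  }
  if (unevaluable > 0L)
    message(unevaluable, " pair(s) dropped under strict end policy: ",
            "flank not evaluable on both sides")
  pairs[keep, , drop = FALSE]
}

#' Merge pairwise orthologue lists against the reference genome
#'
#' One row per reference gene that has a synteny-passing partner in every
#' other species, ordered by reference genome coordinates (chromosome,
#' then start).  Duplicate partner claims within a species violate
#' one-to-one and cause all involved rows to be dropped (reported).
#'
#' @param pairwise Named list (species -> data frame with columns `a` =
#'   reference gene, `b` = partner).
#' @param ref_coords Reference coordinate table.
#' @param reference Reference species name (first column of the output).
#' @return Data frame: `ref_gene` plus one partner column per species.
#' @export
merge_orthologues <- function(pairwise, ref_coords, reference = "reference") {
  check_coords(ref_coords)
  if (!length(names(pairwise)) || any(!nzchar(names(pairwise))))
    stop("'pairwise' must be a named list keyed by species")
  clean <- lapply(names(pairwise), function(sp) {
    p <- pairwise[[sp]]
    dup <- p$a %in% p$a[duplicated(p$a)] | p$b %in% p$b[duplicated(p$b)]
    if (any(dup))
      message(sum(dup), " row(s) dropped for species ", sp,
              ": duplicate partner claims violate one-to-one")
    p[!dup, , drop = FALSE]
  })
  names(clean) <- names(pairwise)
  common <- Reduce(intersect, lapply(clean, `[[`, "a"))
  ord <- ref_coords[order(ref_coords$chrom, ref_coords$start), "gene"]
  common <- ord[ord %in% common]
  out <- data.frame(ref_gene = common)
  for (sp in names(clean))
    out[[sp]] <- clean[[sp]]$b[match(common, clean[[sp]]$a)]
  attr(out, "reference") <- reference
  out
}
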