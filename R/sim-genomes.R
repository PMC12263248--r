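#' Simulate gene orders and protein hit tables with known orthology
#'
#' Builds a test harness for the orthology pipeline: a reference genome
#' plus four other species whose gene orders are the reference order with
#' `rearrangement_events` random block moves, pairwise BLAST-tabular hit
#' tables in both directions, and the true orthologue map.  Every gene's
#' best-scoring hit is its true orthologue; with probability
#' `paralog_rate` a decoy paralog hit is added with strictly lower bit
#' score, lower identity, shorter alignment, and an E-value straddling the
#' 1e-7 cutoff (half at 1e-8, half at 1e-6), so decoys survive E-value
#' filtering half the time yet can never win reciprocal-best-hit ranking.
#'
#' @param n_genes Number of genes (>= 10).
#' @param rearrangement_events Number of 3-gene block moves applied to each
#'   non-reference genome.
#' @param paralog_rate Per-gene, per-direction probability of a decoy hit.
#' @param seed Optional integer seed.
#' @param species Species names; the first is the reference.
#' @return Object of class `sim_genomes`: `coords` (named list of BED-style
#'   0-based half-open data frames gene/chrom/start/end), `hits` (per
#'   non-reference species, list with `ab` = reference-to-species and `ba`
#'   tables, 12-column BLAST format), `lengths` (named list of
#'   gene/length protein-length tables), `truth` (ref_gene, species,
#'   partner), `reference`.
#' @export
simulate_synteny_genomes <- function(n_genes, rearrangement_events = 0L,
                                     paralog_rate = 0, seed = NULL,
                                     species = c("plac1", "nonplac1",
                                                 "plac2", "nonplac2",
                                                 "outgroup")) {
  if (n_genes < 10L) stop("'n_genes' must be >= 10")
  if (paralog_rate < 0 || paralog_rate > 1)
    stop("'paralog_rate' must be a probability")
  if (!is.null(seed)) set.seed(seed)
  ref <- species[1]
  gid <- sprintf("g%05d", seq_len(n_genes))
  plen <- 200L + (seq_len(n_genes) %% 7L) * 25L   # protein lengths, aa

  block_move <- function(ord, block = 3L) {
    n <- length(ord)
    start <- sample.int(n - block + 1L, 1L)
    blk <- ord[start:(start + block - 1L)]
    rest <- ord[-(start:(start + block - 1L))]
    at <- sample.int(length(rest) + 1L, 1L) - 1L
    append(rest, blk, after = at)
  }

  coords <- list()
  lengths <- list()
  orders <- list()
  for (sp in species) {
    ord <- seq_len(n_genes)
    if (sp != ref && rearrangement_events > 0L)
      for (k in seq_len(rearrangement_events)) ord <- block_move(ord)
    orders[[sp]] <- ord
    g <- paste0(sp, ":", gid[ord])
    coords[[sp]] <- data.frame(
      gene = g, chrom = "chr1",
      start = (seq_along(ord) - 1L) * 1000L,
      end = (seq_along(ord) - 1L) * 1000L + 900L)
    lengths[[sp]] <- data.frame(gene = paste0(sp, ":", gid),
                                length = plen)
  }

  hit_row <- function(q, s, qlen, frac, pident, evalue, bits) {
    al <- as.integer(round(frac * qlen))
    data.frame(qseqid = q, sseqid = s, pident = pident, length = al,
               mismatch = as.integer(round(al * (100 - pident) / 100)),
               gapopen = 0L, qstart = 1L, qend = al, sstart = 1L,
               send = al, evalue = evalue, bitscore = bits)
  }

  direction <- function(sp_q, sp_s) {
    i <- seq_len(n_genes)
    true <- hit_row(paste0(sp_q, ":", gid), paste0(sp_s, ":", gid),
                    plen, 0.95, 88 + (i %% 10),
                    10^-(50 + (i %% 20)), 500 + (i %% 40))
    decoy_on <- stats::runif(n_genes) < paralog_rate
    if (any(decoy_on)) {
      di <- which(decoy_on)
      subj <- vapply(di, function(j)
        sample(setdiff(seq_len(n_genes), j), 1L), integer(1))
      dec <- hit_row(paste0(sp_q, ":", gid[di]),
                     paste0(sp_s, ":", gid[subj]),
                     plen[di], 0.5, 55,
                     ifelse(seq_along(di) %% 2L == 0L, 1e-8, 1e-6),
                     200 + (di %% 30))
      true <- rbind(true, dec)
    }
    true[order(true$qseqid, -true$bitscore), ]
  }

  hits <- list()
  truth <- NULL
  for (sp in species[-1]) {
    hits[[sp]] <- list(ab = direction(ref, sp), ba = direction(sp, ref))
    truth <- rbind(truth, data.frame(ref_gene = paste0(ref, ":", gid),
                                     species = sp,
                                     partner = paste0(sp, ":", gid)))
  }
  structure(list(coords = coords, hits = hits, lengths = lengths,
                 truth = truth, reference = ref),
            class = "sim_genomes")
}
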