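# Filtering, deduplication, classification and aggregation of crosslink
# identifications, and triangulation of a binding region from interlink
# detection frequencies.

#' Filter crosslink identifications by confidence
#'
#' Keeps records with `id_score > min_id_score` and `fdr < max_fdr`
#' (strict inequalities on both boundaries).
#'
#' @param records crosslink records (see [read_xlink_table()]).
#' @param min_id_score minimum identification score, exclusive (default 20).
#' @param max_fdr maximum false-discovery rate, exclusive (default 0.05).
#' @return Filtered records.
#' @export
filter_links <- function(records, min_id_score = 20, max_fdr = 0.05) {
  keep <- records$id_score > min_id_score & records$fdr < max_fdr
  records[keep, , drop = FALSE]
}

# canonical side order: lexicographic by (protein, position, peptide)
#' @noRd
canonicalize_links <- function(records) {
  ka <- paste(records$protein_a, formatC(records$pos_a, width = 9, flag = "0"),
              records$peptide_a)
  kb <- paste(records$protein_b, formatC(records$pos_b, width = 9, flag = "0"),
              records$peptide_b)
  swap <- ka > kb
  if (any(swap)) {
    tmp <- records[swap, c("protein_a", "pos_a", "peptide_a")]
    records[swap, c("protein_a", "pos_a", "peptide_a")] <-
      records[swap, c("protein_b", "pos_b", "peptide_b")]
    records[swap, c("protein_b", "pos_b", "peptide_b")] <- tmp
  }
  records
}

#' Collapse duplicate identifications to unique detections
#'
#' Identifications that differ only in precursor charge state (or are
#' repeated verbatim, e.g. technical duplicates within a replicate)
#' collapse to one detection. Distinct peptide forms covering the same
#' linked residue pair (different missed-cleavage lengths) and detections
#' from different biological replicates remain separate. Within a
#' duplicate group the representative carries the best confidence
#' (highest id score, then lowest FDR).
#'
#' @param records crosslink records.
#' @return One representative record per unique detection.
#' @export
deduplicate_links <- function(records) {
  if (nrow(records) == 0) return(records)
  records <- canonicalize_links(records)
  key <- paste(records$protein_a, records$pos_a, records$peptide_a,
               records$protein_b, records$pos_b, records$peptide_b,
               records$replicate, sep = "\r")
  ord <- order(key, -records$id_score, records$fdr,
               seq_len(nrow(records)))
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(key[ord]), , drop = FALSE]
  out[order(as.integer(rownames(out))), , drop = FALSE]
}

#' Classify detections into a link map
#'
#' Aggregates unique detections into residue-pair keys with detection
#' counts and categories: `interlink` (residues on the two different
#' proteins), `intralink` (same protein, or the same position pair within
#' one protein reached via different peptides), and `symmetric_dimer`
#' (identical position linked to itself, evidence of a homodimer).
#'
#' @param records unique detections (after [deduplicate_links()]).
#' @param protein_ids character vector naming the two components, e.g.
#'   `c("CaM", "AKAP79")`.
#' @return A `link_map`: data frame with columns `protein_a`, `pos_a`,
#'   `protein_b`, `pos_b`, `count`, `category`, carrying `protein_ids` as
#'   an attribute.
#' @export
classify_links <- function(records, protein_ids) {
  if (length(protein_ids) != 2) stopf("protein_ids must name two components")
  unknown <- setdiff(unique(c(records$protein_a, records$protein_b)),
                     protein_ids)
  if (length(unknown) > 0)
    stopf("record names unknown protein(s): %s",
          paste(unknown, collapse = ", "))
  records <- canonicalize_links(records)
  if (nrow(records) == 0) {
    map <- data.frame(protein_a = character(), pos_a = integer(),
                      protein_b = character(), pos_b = integer(),
                      count = integer(), category = character(),
                      stringsAsFactors = FALSE)
    attr(map, "protein_ids") <- protein_ids
    class(map) <- c("link_map", "data.frame")
    return(map)
  }
  key <- paste(records$protein_a, records$pos_a,
               records$protein_b, records$pos_b, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(as.character(agg$key), "\r",
                                   fixed = TRUE))
  map <- data.frame(protein_a = parts[, 1],
                    pos_a = as.integer(parts[, 2]),
                    protein_b = parts[, 3],
                    pos_b = as.integer(parts[, 4]),
                    count = agg$Freq,
                    stringsAsFactors = FALSE)
  map$category <- ifelse(map$protein_a != map$protein_b, "interlink",
                         ifelse(map$pos_a == map$pos_b, "symmetric_dimer",
                                "intralink"))
  map <- map[order(map$protein_a, map$pos_a, map$protein_b, map$pos_b), ,
             drop = FALSE]
  rownames(map) <- NULL
  attr(map, "protein_ids") <- protein_ids
  class(map) <- c("link_map", "data.frame")
  map
}

#' Rank residue-pair links by detection frequency
#'
#' @param linkmap a `link_map` from [classify_links()].
#' @param partner_protein,partner_pos optional restriction to keys
#'   involving one residue (e.g. CaM lysine 94).
#' @return The link-map rows sorted by descending count; ties broken by
#'   ascending position on the other protein (then own protein/position).
#' @export
link_frequency <- function(linkmap, partner_protein = NULL,
                           partner_pos = NULL) {
  map <- as.data.frame(linkmap)
  if (!is.null(partner_protein)) {
    hit_a <- map$protein_a == partner_protein
    hit_b <- map$protein_b == partner_protein
    if (!is.null(partner_pos)) {
      hit_a <- hit_a & map$pos_a == partner_pos
      hit_b <- hit_b & map$pos_b == partner_pos
    }
    map <- map[hit_a | hit_b, , drop = FALSE]
    other_pos <- ifelse(map$protein_a == partner_protein &
                          (is.null(partner_pos) | map$pos_a == partner_pos),
                        map$pos_b, map$pos_a)
  } else {
    other_pos <- map$pos_b
  }
  ord <- order(-map$count, other_pos, map$pos_a, map$pos_b)
  out <- map[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Triangulate a binding site from interlink frequencies
#'
#' Detection-count-weighted mean of the target-protein residue positions
#' over all interlinks touching the target, with a percentile bootstrap
#' confidence interval obtained by resampling detections.
#'
#' @param linkmap a `link_map`.
#' @param target_protein protein whose binding region is triangulated.
#' @param partner_pos optional residue number on the partner protein:
#'   when given, only interlinks through that reference residue (the
#'   cross-linking hot-spot) contribute.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return List with `position` (weighted mean), `ci` (two-sided
#'   percentile interval), `n_detections` and `n_pairs`.
#' @export
triangulate_site <- function(linkmap, target_protein, partner_pos = NULL,
                             n_boot = 1000, conf = 0.95, seed = NULL) {
  map <- as.data.frame(linkmap)
  inter <- map[map$category == "interlink" &
                 (map$protein_a == target_protein |
                    map$protein_b == target_protein), , drop = FALSE]
  if (!is.null(partner_pos)) {
    ppos <- ifelse(inter$protein_a == target_protein, inter$pos_b,
                   inter$pos_a)
    inter <- inter[ppos == partner_pos, , drop = FALSE]
  }
  if (nrow(inter) == 0)
    stopf("no interlinks touch protein '%s'", target_protein)
  pos <- ifelse(inter$protein_a == target_protein, inter$pos_a, inter$pos_b)
  detections <- rep(pos, inter$count)
  est <- mean(detections)
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(detections[sample.int(length(detections),
                                 replace = TRUE)])
    }, numeric(1))
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  list(position = est, ci = ci, n_detections = length(detections),
       n_pairs = nrow(inter))
}

#' Tally detections per category
#'
#' @param linkmap a `link_map`.
#' @return List with `total`, `n_interlink`, `n_intralink_a`,
#'   `n_intralink_b` (intralinks within the first and second protein of
#'   the map's `protein_ids`), and `n_symmetric`. The total equals the
#'   number of unique detections and is the sum of the parts.
#' @export
count_summary <- function(linkmap) {
  map <- as.data.frame(linkmap)
  ids <- attr(linkmap, "protein_ids")
  tot <- function(sel) if (any(sel)) sum(map$count[sel]) else 0L
  n_inter <- tot(map$category == "interlink")
  n_sym <- tot(map$category == "symmetric_dimer")
  n_ia <- tot(map$category == "intralink" & map$protein_a == ids[1])
  n_ib <- tot(map$category == "intralink" & map$protein_a == ids[2])
  list(total = n_inter + n_ia + n_ib + n_sym,
       n_interlink = n_inter,
       n_intralink_a = n_ia,
       n_intralink_b = n_ib,
       n_symmetric = n_sym)
}

#' Share of interlinks mediated by one hot-spot residue
#'
#' Reports the fraction of interlink detections, and of unique interlink
#' residue pairs, that involve the given residue. Both bases are reported
#' because multiplicity-weighted and pair-based percentages can differ
#' substantially.
#'
#' @param linkmap a `link_map`.
#' @param protein,pos the hot-spot residue.
#' @return List with `pct_detections` and `pct_pairs` (percent).
#' @export
hotspot_share <- function(linkmap, protein, pos) {
  map <- as.data.frame(linkmap)
  inter <- map[map$category == "interlink", , drop = FALSE]
  if (nrow(inter) == 0) return(list(pct_detections = NA_real_,
                                    pct_pairs = NA_real_))
  at <- (inter$protein_a == protein & inter$pos_a == pos) |
    (inter$protein_b == protein & inter$pos_b == pos)
  list(pct_detections = 100 * sum(inter$count[at]) / sum(inter$count),
       pct_pairs = 100 * sum(at) / nrow(inter))
}
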