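# End-to-end orchestration: combine crosslink triangulation with motif
# scanning, and assemble per-structure geometry/compactness reports.

#' Site-mapping run: crosslink triangulation + motif scan
#'
#' Filters and deduplicates a crosslink table, classifies links,
#' triangulates the binding region on the target protein from interlink
#' detection frequencies, scans the target sequence with a motif matrix,
#' and flags concordance when the best-scoring scan anchor falls within
#' `concordance_window` residues of the triangulated position.
#'
#' @param config list with elements:
#'   `xlink` (crosslink records or a TSV path),
#'   `sequence` (sequence records or a FASTA path),
#'   `proteins` (the two component names; the first is the scan/
#'   triangulation target unless `target` is given),
#'   `target` (optional target protein id),
#'   `min_id_score` (default 20), `max_fdr` (default 0.05),
#'   `matrix` (a [motif_matrix()] or file path; default
#'   [build_default_matrix()]),
#'   `threshold` (scan threshold, default 0.5),
#'   `sequence_offset` (residue number of the first sequence letter,
#'   default 1),
#'   `concordance_window` (default 25),
#'   `seed` (bootstrap seed, default 1), `n_boot` (default 1000).
#' @return Report list (JSON-ready): filter bookkeeping, category
#'   totals, hot-spot table, triangulation block, scan hits and the
#'   concordance flag, plus a provenance block with every threshold
#'   consumed.
#' @export
run_site_mapping <- function(config) {
  cfg <- config
  cfg$min_id_score <- cfg$min_id_score %||% 20
  cfg$max_fdr <- cfg$max_fdr %||% 0.05
  cfg$threshold <- cfg$threshold %||% 0.5
  cfg$concordance_window <- cfg$concordance_window %||% 25
  cfg$sequence_offset <- cfg$sequence_offset %||% 1L
  cfg$seed <- cfg$seed %||% 1L
  cfg$n_boot <- cfg$n_boot %||% 1000L
  records <- if (is.character(cfg$xlink)) read_xlink_table(cfg$xlink)
    else cfg$xlink
  seqs <- if (is.character(cfg$sequence)) read_fasta(cfg$sequence)
    else cfg$sequence
  mat <- if (is.null(cfg$matrix)) build_default_matrix()
    else if (is.character(cfg$matrix)) read_motif_matrix(cfg$matrix)
    else cfg$matrix
  target <- cfg$target %||% cfg$proteins[1]

  n_in <- nrow(records)
  filtered <- filter_links(records, cfg$min_id_score, cfg$max_fdr)
  unique_det <- deduplicate_links(filtered)
  map <- classify_links(unique_det, cfg$proteins)
  counts <- count_summary(map)
  freq <- link_frequency(map)
  inter_freq <- freq[freq$category == "interlink", , drop = FALSE]

  # cross-linking hot-spot: partner-protein residue carrying the most
  # interlink detections; it is the reference point for triangulation
  partner <- setdiff(cfg$proteins, target)
  hotspot_pos <- NULL
  if (nrow(inter_freq) > 0) {
    ppos <- ifelse(inter_freq$protein_a == partner, inter_freq$pos_a,
                   inter_freq$pos_b)
    tal <- tapply(inter_freq$count, ppos, sum)
    hotspot_pos <- as.integer(names(tal)[which.max(tal)])
  }

  tri <- tryCatch(triangulate_site(map, target, partner_pos = hotspot_pos,
                                   n_boot = cfg$n_boot, seed = cfg$seed),
                  error = function(e) NULL)
  tri_all <- tryCatch(triangulate_site(map, target, n_boot = cfg$n_boot,
                                       seed = cfg$seed),
                      error = function(e) NULL)

  target_rec <- seqs[seqs$id == target, , drop = FALSE]
  if (nrow(target_rec) == 0) target_rec <- seqs[1, , drop = FALSE]
  scan <- scan_sequence(mat, target_rec, threshold = cfg$threshold,
                        offset = cfg$sequence_offset)

  concordant <- NA
  if (!is.null(tri) && nrow(scan) > 0)
    concordant <- abs(scan$anchor_pos[1] - tri$position) <=
      cfg$concordance_window

  list(
    counts = list(records_in = n_in, records_filtered = nrow(filtered),
                  unique_detections = nrow(unique_det)),
    categories = counts,
    link_frequency = head_as_list(inter_freq, 25),
    hotspot = if (is.null(hotspot_pos)) NULL
      else c(list(partner_protein = partner, partner_pos = hotspot_pos),
             hotspot_share(map, partner, hotspot_pos)),
    triangulation = if (is.null(tri)) list(available = FALSE)
      else c(list(available = TRUE), tri),
    triangulation_all_interlinks = if (is.null(tri_all)) NULL
      else tri_all,
    scan = list(n_hits = nrow(scan),
                top_anchor = if (nrow(scan) > 0) scan$anchor_pos[1]
                  else NA_integer_,
                hits = head_as_list(scan, 25)),
    concordant = concordant,
    provenance = list(min_id_score = cfg$min_id_score,
                      max_fdr = cfg$max_fdr,
                      scan_threshold = cfg$threshold,
                      concordance_window = cfg$concordance_window,
                      sequence_offset = cfg$sequence_offset,
                      seed = cfg$seed, n_boot = cfg$n_boot,
                      target = target))
}

#' @noRd
head_as_list <- function(df, n) {
  df <- utils::head(as.data.frame(df), n)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Structure report: helix geometry, compactness and copy agreement
#'
#' Assembles the per-residue dihedral/class table, backbone H-bond
#' offsets, terminal anchor spacing and hydrophobic-face coherence for a
#' bound peptide chain, exposed and buried surface areas between two
#' components, and (optionally) the RMSD between two copies of the
#' complex.
#'
#' @param config list with elements:
#'   `structure` (a [structure3d()] or file path),
#'   `peptide_chain`, `partner_chain` (chain ids),
#'   `range` (optional peptide residue subset),
#'   `anchors` (anchor residue numbers, e.g. `c(79, 82, 85, 86)`),
#'   `copies` (optional list `list(a = chains, b = chains)` for
#'   copy-vs-copy RMSD), `regions` (optional named list of residue ranges
#'   for per-region RMSD),
#'   `probe` (default 1.4), `n_points` (default 960),
#'   `hbond_distance` (default 3.5), `hbond_angle` (default 120),
#'   `psi_310` (default -37), `include_het` (include HETATM ions in the
#'   partner component, default TRUE).
#' @return Report list (JSON-ready) with a provenance block.
#' @export
run_structure_report <- function(config) {
  cfg <- config
  cfg$probe <- cfg$probe %||% 1.4
  cfg$n_points <- cfg$n_points %||% 960
  cfg$hbond_distance <- cfg$hbond_distance %||% 3.5
  cfg$hbond_angle <- cfg$hbond_angle %||% 120
  cfg$psi_310 <- cfg$psi_310 %||% -37
  cfg$include_het <- cfg$include_het %||% TRUE
  struct <- if (is.character(cfg$structure)) read_structure(cfg$structure)
    else cfg$structure

  dih <- compute_dihedrals(struct, cfg$peptide_chain, cfg$range)
  dih <- classify_helix(dih, psi_310 = cfg$psi_310)
  hb <- detect_backbone_hbonds(struct, cfg$peptide_chain,
                               distance_cutoff = cfg$hbond_distance,
                               angle_cutoff = cfg$hbond_angle,
                               resno = cfg$range)
  spacing <- NULL
  face <- NULL
  if (!is.null(cfg$anchors) && length(cfg$anchors) >= 2) {
    spacing <- anchor_spacing(struct, cfg$peptide_chain,
                              min(cfg$anchors), max(cfg$anchors))
    face <- tryCatch(hydrophobic_face_check(struct, cfg$peptide_chain,
                                            cfg$anchors),
                     error = function(e) list(coherent = NA,
                                              max_pairwise_angle = NA))
  }

  surface <- NULL
  if (!is.null(cfg$partner_chain)) {
    sel_p <- select_atoms(struct, chain = cfg$partner_chain,
                          het = cfg$include_het)
    sel_q <- select_atoms(struct, chain = cfg$peptide_chain)
    partner_alone <- sasa(struct, sel_p, probe = cfg$probe,
                          n_points = cfg$n_points)
    burial <- buried_area(struct, sel_p, sel_q, probe = cfg$probe,
                          n_points = cfg$n_points)
    surface <- list(partner_exposed_alone = partner_alone$total_area,
                    partner_exposed_in_complex = burial$area_a_complex,
                    buried_partner = burial$buried_a,
                    buried_peptide = burial$buried_b,
                    mean_interface = burial$mean_interface)
  }

  copies <- NULL
  if (!is.null(cfg$copies)) {
    overall <- region_rmsd(struct, cfg$copies$a, cfg$copies$b)
    per_region <- NULL
    if (!is.null(cfg$regions)) {
      per_region <- lapply(cfg$regions, function(rng) {
        r <- region_rmsd(struct, cfg$copies$a, cfg$copies$b, resno = rng)
        list(rmsd = r$rmsd, n_pairs = r$n_pairs, n_skipped = r$n_skipped)
      })
    }
    copies <- list(rmsd = overall$rmsd, n_pairs = overall$n_pairs,
                   n_skipped = overall$n_skipped, regions = per_region)
  }

  n_helical <- sum(dih$class %in% c("alpha", "three10"))
  list(
    dihedrals = head_as_list(
      dih[, c("resno", "resid", "phi", "psi", "class")], nrow(dih)),
    n_right_handed_helical = n_helical,
    n_alpha = sum(dih$class == "alpha"),
    n_three10 = sum(dih$class == "three10"),
    hbonds = head_as_list(hb, nrow(hb)),
    hbond_offsets = as.list(table(hb$offset)),
    anchor_spacing = spacing,
    face = face,
    surface = surface,
    copies = copies,
    cell = struct$cell,
    provenance = list(probe = cfg$probe, n_points = cfg$n_points,
                      hbond_distance = cfg$hbond_distance,
                      hbond_angle = cfg$hbond_angle,
                      psi_310 = cfg$psi_310,
                      peptide_chain = cfg$peptide_chain,
                      partner_chain = cfg$partner_chain,
                      anchors = cfg$anchors))
}
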