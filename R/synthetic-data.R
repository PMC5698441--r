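# Seeded generators for every input class the pipeline consumes, each
# returning machine-readable ground truth alongside the data.

#' Backbone torsion plan for an ideal helix
#'
#' @param sequence one-letter residue string.
#' @param phi,psi per-residue backbone torsions in degrees (recycled to
#'   the sequence length). Canonical alpha: (-57, -47); 3-10: (-49, -26).
#' @return Data frame (`helix_plan`) with columns `aa`, `phi`, `psi`.
#' @export
helix_plan <- function(sequence, phi = -57, psi = -47) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n < 2) stopf("plan needs at least 2 residues")
  if (!all(aa %in% AA1)) stopf("plan sequence must use canonical residues")
  plan <- data.frame(aa = aa, phi = rep_len(phi, n), psi = rep_len(psi, n),
                     stringsAsFactors = FALSE)
  if (any(!is.finite(plan$phi)) || any(!is.finite(plan$psi)))
    stopf("plan angles must be finite")
  class(plan) <- c("helix_plan", "data.frame")
  plan
}

# standard backbone geometry (angstroms / degrees)
.helix_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.6, t_c_n_ca_cb = -122.7, omega = 180)

#' Build an ideal peptide from a torsion plan
#'
#' Serial internal-to-Cartesian construction (NeRF): backbone atoms N,
#' CA, C, O (and CB for non-glycines, placed with L-chirality) are placed
#' with standard bond lengths and angles, omega fixed at 180 degrees, and
#' phi/psi taken from the plan. Deterministic.
#'
#' @param plan a [helix_plan()].
#' @param chain chain id for the output (default "A").
#' @param start author residue number of the first residue (default 1).
#' @return A [structure3d()].
#' @export
make_helix <- function(plan, chain = "A", start = 1L) {
  g <- .helix_geom
  n <- nrow(plan)
  N <- CA <- C <- vector("list", n)
  # first residue in a canonical frame
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  C[[1]] <- place_atom(c(0, 0, 1), N[[1]], CA[[1]], g$b_ca_c, g$a_n_ca_c, 0)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], g$b_c_n, g$a_ca_c_n,
                             plan$psi[i])
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], g$b_n_ca,
                              g$a_c_n_ca, g$omega)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], g$b_ca_c,
                             g$a_n_ca_c, plan$phi[i + 1])
  }
  rows <- list()
  for (i in seq_len(n)) {
    resid <- AA1TO3[[plan$aa[i]]]
    rn <- start + i - 1L
    add <- function(ety, esy, xyz) {
      rows[[length(rows) + 1]] <<- data.frame(
        type = "ATOM", chain = chain, resno = rn, insert = "",
        resid = resid, elety = ety, elesy = esy,
        x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
        stringsAsFactors = FALSE)
    }
    add("N", "N", N[[i]])
    add("CA", "C", CA[[i]])
    add("C", "C", C[[i]])
    # carbonyl O opposite the next amide in the peptide plane
    add("O", "O", place_atom(N[[i]], CA[[i]], C[[i]], g$b_c_o, g$a_ca_c_o,
                             plan$psi[i] + 180))
    if (plan$aa[i] != "G")
      add("CB", "C", place_atom(C[[i]], N[[i]], CA[[i]], g$b_ca_cb,
                                g$a_n_ca_cb, g$t_c_n_ca_cb))
  }
  structure3d(do.call(rbind, rows))
}

#' Generate a synthetic proteome with planted motifs
#'
#' Background residues are drawn i.i.d. from `composition`; planted motif
#' strings overwrite the background at recorded positions. The returned
#' truth table, not the sequences, is the reference for recovery tests.
#'
#' @param n_proteins number of sequences.
#' @param length_range inclusive range of sequence lengths.
#' @param n_planted number of planted motifs (at most one per protein).
#' @param motif motif string to plant; the default is the 8-residue
#'   1-4-7-8 consensus of [build_default_matrix()] (window positions of
#'   the matrix anchor through anchor+7).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param composition named per-residue sampling weights (default uniform
#'   over the 20 canonical residues). Letters may be excluded by omission.
#' @return List with `records` (data frame `id`, `desc`, `seq`) and
#'   `truth` (data frame `id`, `anchor_pos`, `motif`).
#' @export
make_proteome <- function(n_proteins, length_range = c(120, 400),
                          n_planted = 0, motif = NULL, seed = 1,
                          composition = NULL) {
  if (is.null(motif)) {
    m <- build_default_matrix()
    cw <- consensus_window(m)
    motif <- substr(cw, m$anchor_offset, m$anchor_offset + 7)
  }
  if (is.null(composition))
    composition <- stats::setNames(rep(1, 20), AA1)
  letters_bg <- names(composition)
  if (n_planted > n_proteins)
    stopf("cannot plant %d motifs in %d proteins", n_planted, n_proteins)
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    if (any(lens < nchar(motif) + 2) && n_planted > 0)
      stopf("motif longer than the shortest protein")
    seqs <- vapply(lens, function(L) {
      paste(sample(letters_bg, L, replace = TRUE,
                   prob = composition / sum(composition)), collapse = "")
    }, character(1))
    ids <- sprintf("synthetic_prot_%03d", seq_len(n_proteins))
    planted_in <- if (n_planted > 0) sort(sample(n_proteins, n_planted))
      else integer(0)
    truth <- data.frame(id = character(), anchor_pos = integer(),
                        motif = character(), stringsAsFactors = FALSE)
    for (p in planted_in) {
      L <- lens[p]
      pos <- sample(seq(4, L - nchar(motif) - 3), 1)  # room for flanks
      substr(seqs[p], pos, pos + nchar(motif) - 1) <- motif
      truth <- rbind(truth, data.frame(id = ids[p], anchor_pos = pos,
                                       motif = motif,
                                       stringsAsFactors = FALSE))
    }
    list(records = data.frame(id = ids, desc = "synthetic", seq = seqs,
                              stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Specification for a synthetic crosslink table
#'
#' The defaults emulate the statistical structure of a two-protein
#' crosslinking experiment with a detection hot-spot: one partner residue
#' accounts for a disproportionate share of interlink detections, the
#' remaining links are spread uniformly, and a stated number of decoy
#' rows fail the confidence filters.
#'
#' @param proteins named lengths of the two components (first = the
#'   protein carrying the hot-spot targets).
#' @param hotspot list with `partner_pos` (residue on the second
#'   protein) and `targets` (named detection counts on the first
#'   protein, names = residue numbers).
#' @param n_interlink total interlink detections including the hot-spot.
#' @param n_intralink_a,n_intralink_b intralink detections within each
#'   protein.
#' @param n_symmetric symmetric (position-to-itself) detections within
#'   the first protein.
#' @param n_below decoy rows failing the id-score/FDR filters.
#' @param replicates number of biological replicates detections are
#'   spread over.
#' @param interlink_range residue window on the first protein that
#'   interlinks fall in (cross-links concentrate near the interface; the
#'   default emulates a binding region in the protein's N-terminus).
#' @param seed integer seed.
#' @return List of class `xlink_spec`.
#' @export
xlink_spec <- function(proteins = c(AKAP79 = 427, CaM = 149),
                       hotspot = list(partner_pos = 94,
                                      targets = c("90" = 4, "96" = 7,
                                                  "99" = 16)),
                       n_interlink = 47, n_intralink_a = 148,
                       n_intralink_b = 13, n_symmetric = 5,
                       n_below = 30, replicates = 3,
                       interlink_range = c(41, 177), seed = 1) {
  spec <- list(proteins = proteins, hotspot = hotspot,
               n_interlink = n_interlink, n_intralink_a = n_intralink_a,
               n_intralink_b = n_intralink_b, n_symmetric = n_symmetric,
               n_below = n_below, replicates = replicates,
               interlink_range = interlink_range, seed = seed)
  if (any(unlist(spec[c("n_interlink", "n_intralink_a", "n_intralink_b",
                        "n_symmetric", "n_below")]) < 0))
    stopf("counts must be nonnegative")
  if (!is.null(hotspot) && sum(hotspot$targets) > n_interlink)
    stopf("hot-spot detections exceed the interlink total")
  class(spec) <- "xlink_spec"
  spec
}

#' Generate a synthetic crosslink identification table
#'
#' Every specified detection becomes one high-confidence row (id score in
#' (20, 45], FDR in [0, 0.05)); unique detections of the same residue
#' pair are realized as distinct peptide forms (different flank lengths)
#' spread over replicates. A random subset of detections additionally
#' appears at a second charge state (rows that collapse under
#' [deduplicate_links()]), and `n_below` decoy rows fail the filters.
#'
#' @param spec an [xlink_spec()].
#' @return List with `records` (rows in randomized order) and `truth`
#'   (the per-category unique detection counts and the hot-spot table).
#' @export
make_xlink_table <- function(spec = xlink_spec()) {
  pnames <- names(spec$proteins)
  plens <- as.integer(spec$proteins)
  with_seed(spec$seed, {
    seqs <- stats::setNames(lapply(plens, function(L) {
      sample(AA1, L, replace = TRUE)
    }), pnames)
    peptide_form <- function(prot, pos, form) {
      # deterministic distinct flank lengths per form index
      la <- 3 + (form - 1) %% 5
      lb <- 4 + (form - 1) %/% 5
      s <- seqs[[prot]]
      lo <- max(1, pos - la)
      hi <- min(length(s), pos + lb)
      paste(s[lo:hi], collapse = "")
    }
    rows <- list()
    emit <- function(prot_a, pos_a, prot_b, pos_b, form, passing) {
      rows[[length(rows) + 1]] <<- data.frame(
        protein_a = prot_a, pos_a = pos_a,
        peptide_a = peptide_form(prot_a, pos_a, form),
        protein_b = prot_b, pos_b = pos_b,
        peptide_b = peptide_form(prot_b, pos_b, form),
        id_score = if (passing) stats::runif(1, 20.5, 45)
          else sample(c(stats::runif(1, 5, 20), 20))[1],
        fdr = if (passing) stats::runif(1, 0, 0.049)
          else sample(c(stats::runif(1, 0.05, 0.5), 0.05))[1],
        replicate = sample(spec$replicates, 1),
        charge = sample(3:4, 1),
        stringsAsFactors = FALSE)
    }
    emit_pair_detections <- function(prot_a, pos_a, prot_b, pos_b, count) {
      for (f in seq_len(count)) emit(prot_a, pos_a, prot_b, pos_b, f, TRUE)
    }
    # hot-spot interlinks
    n_hot <- 0
    if (!is.null(spec$hotspot)) {
      for (t in names(spec$hotspot$targets)) {
        emit_pair_detections(pnames[1], as.integer(t), pnames[2],
                             spec$hotspot$partner_pos,
                             spec$hotspot$targets[[t]])
        n_hot <- n_hot + spec$hotspot$targets[[t]]
      }
    }
    hot_positions <- if (is.null(spec$hotspot)) integer(0)
      else as.integer(names(spec$hotspot$targets))
    # background interlinks: unique residue pairs away from the hot-spot
    n_bg <- spec$n_interlink - n_hot
    bg_window <- seq(max(1, spec$interlink_range[1]),
                     min(plens[1], spec$interlink_range[2]))
    used <- character(0)
    k <- 0
    while (k < n_bg) {
      pa <- sample(setdiff(bg_window, hot_positions), 1)
      pb <- sample(seq_len(plens[2]), 1)
      if (!is.null(spec$hotspot) && pb == spec$hotspot$partner_pos) next
      key <- paste(pa, pb)
      if (key %in% used) next
      used <- c(used, key)
      emit(pnames[1], pa, pnames[2], pb, 1, TRUE)
      k <- k + 1
    }
    # intralinks
    intra <- function(prot, len, count) {
      used <- character(0)
      k <- 0
      while (k < count) {
        p <- sort(sample(len, 2))
        key <- paste(p, collapse = " ")
        if (key %in% used) next
        used <- c(used, key)
        emit(prot, p[1], prot, p[2], 1, TRUE)
        k <- k + 1
      }
    }
    intra(pnames[1], plens[1], spec$n_intralink_a)
    intra(pnames[2], plens[2], spec$n_intralink_b)
    # symmetric homodimer links in the first protein
    if (spec$n_symmetric > 0) {
      sym_pos <- sample(plens[1], min(3, spec$n_symmetric))
      for (f in seq_len(spec$n_symmetric)) {
        p <- sym_pos[(f - 1) %% length(sym_pos) + 1]
        form <- (f - 1) %/% length(sym_pos) + 1
        emit(pnames[1], p, pnames[1], p, form, TRUE)
      }
    }
    # decoys failing score/FDR filters (include exact boundary values)
    for (f in seq_len(spec$n_below)) {
      pa <- sample(plens[1], 1)
      pb <- sample(plens[2], 1)
      emit(pnames[1], pa, pnames[2], pb, f %% 8 + 1, FALSE)
    }
    records <- do.call(rbind, rows)
    # charge-state duplicates of a third of the passing rows: same
    # detection, different precursor charge
    passing <- which(records$id_score > 20 & records$fdr < 0.05)
    dup_idx <- sample(passing, floor(length(passing) / 3))
    dups <- records[dup_idx, , drop = FALSE]
    dups$charge <- ifelse(dups$charge == 3, 4L, 3L)
    records <- rbind(records, dups)
    records <- records[sample(nrow(records)), , drop = FALSE]
    rownames(records) <- NULL
    truth <- list(proteins = pnames,
                  n_interlink = spec$n_interlink,
                  n_intralink_a = spec$n_intralink_a,
                  n_intralink_b = spec$n_intralink_b,
                  n_symmetric = spec$n_symmetric,
                  total = spec$n_interlink + spec$n_intralink_a +
                    spec$n_intralink_b + spec$n_symmetric,
                  hotspot = spec$hotspot)
    list(records = records, truth = truth)
  })
}

#' Generate a synthetic concentration-response curve
#'
#' `y = model(x; params) + N(0, (noise_sd * range)^2)` where `range` is
#' the noiseless response range; deterministic per seed.
#'
#' @param model `"hill_inhibition"`, `"hill_activation"` or `"coop_mm"`.
#' @param params named parameter list for the model function.
#' @param x_grid concentrations (positive, ascending).
#' @param noise_sd Gaussian noise as a fraction of the response range
#'   (default 0).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return Data frame with columns `x`, `y`; the generating parameters
#'   are attached as attribute `truth`.
#' @export
make_binding_curve <- function(model = c("hill_inhibition",
                                         "hill_activation", "coop_mm"),
                               params, x_grid, noise_sd = 0, seed = 1) {
  model <- match.arg(model)
  f <- switch(model, hill_inhibition = hill_inhibition,
              hill_activation = hill_activation, coop_mm = coop_mm)
  y0 <- do.call(f, c(list(x = x_grid), params))
  y <- if (noise_sd > 0) {
    with_seed(seed,
              y0 + stats::rnorm(length(y0),
                                sd = noise_sd * diff(range(y0))))
  } else y0
  out <- data.frame(x = x_grid, y = y)
  attr(out, "truth") <- c(list(model = model), params)
  out
}
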