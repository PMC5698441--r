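# Readers and writers for the external formats the pipeline touches.
# All downstream modules consume the domain objects produced here.

#' Read protein sequences from FASTA
#'
#' Records are validated against the 20 canonical one-letter amino-acid
#' codes plus X (unknown). Lowercase letters are uppercased and whitespace
#' stripped before validation.
#'
#' @param path FASTA file.
#' @return Data frame with columns `id`, `desc`, `seq` (one row per record).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("failed to read FASTA %s: %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0) stopf("empty FASTA file: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  ok <- c(AA1, "X")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < 1) stopf("record '%s' is empty", ids[i])
    letters_i <- strsplit(seqs[i], "")[[1]]
    bad <- which(!(letters_i %in% ok))
    if (length(bad) > 0)
      stopf("illegal residue letter '%s' in record '%s' at position %d",
            letters_i[bad[1]], ids[i], bad[1])
  }
  data.frame(id = ids, desc = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' Sequence lines wrap at 60 columns, so that a read/write cycle is
#' byte-identical on wrapped files.
#'
#' @param records data frame with columns `id`, `desc`, `seq` as returned
#'   by [read_fasta()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nchar(records$desc %||% "") > 0,
                       paste(records$id, records$desc),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read macromolecular coordinates (PDB or mmCIF)
#'
#' Parsing is delegated to \pkg{bio3d}; the result is converted to the
#' package's [structure3d()] container. Alternate locations are resolved by
#' keeping the highest-occupancy conformer (ties: first encountered). The
#' crystallographic unit cell and space group are read from the CRYST1
#' record (PDB) or the `_cell`/`_symmetry` categories (mmCIF).
#'
#' @param path coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A [structure3d()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  raw <- if (format == "pdb") {
    tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                              rm.alt = FALSE,
                                              verbose = FALSE)),
             error = function(e) stopf("failed to parse PDB %s: %s", path,
                                       conditionMessage(e)))
  } else {
    tryCatch(suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
             error = function(e) stopf("failed to parse mmCIF %s: %s", path,
                                       conditionMessage(e)))
  }
  a <- raw$atom
  atoms <- data.frame(
    type = a$type,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    elesy = guess_element(a$elesy, a$elety),
    alt = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  cell <- read_cell(path, format)
  structure3d(atoms, cell = cell$cell, spacegroup = cell$spacegroup)
}

#' @noRd
guess_element <- function(elesy, elety) {
  out <- elesy
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    guess <- sub("^[0-9]*", "", elety[bad])
    guess <- substr(gsub("[^A-Za-z]", "", guess), 1, 1)
    out[bad] <- toupper(guess)
  }
  out
}

# keep the highest-occupancy alternate conformer per atom site
#' @noRd
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, atoms$resid)
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' @noRd
read_cell <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (length(cl) == 0) return(list(cell = NULL, spacegroup = NULL))
    cl <- cl[1]
    cell <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                         substr(cl, 25, 33), substr(cl, 34, 40),
                         substr(cl, 41, 47), substr(cl, 48, 54)))
    sg <- trimws(substr(cl, 56, 66))
    list(cell = cell, spacegroup = if (nzchar(sg)) sg else NULL)
  } else {
    val <- function(tag) {
      m <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
      if (length(m) == 0) return(NA_real_)
      as.numeric(strsplit(trimws(m[1]), "\\s+")[[1]][2])
    }
    cell <- c(val("_cell.length_a"), val("_cell.length_b"),
              val("_cell.length_c"), val("_cell.angle_alpha"),
              val("_cell.angle_beta"), val("_cell.angle_gamma"))
    sgl <- grep("^_symmetry.space_group_name", lines, value = TRUE)
    sg <- if (length(sgl) > 0)
      gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sgl[1]))) else NULL
    if (all(is.na(cell))) return(list(cell = NULL, spacegroup = sg))
    list(cell = cell, spacegroup = sg)
  }
}

#' Write a structure to PDB format
#'
#' @param struct a [structure3d()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   type = a$type,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno,
                   resid = a$resid,
                   eleno = seq_len(nrow(a)),
                   elety = a$elety,
                   chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$occ, b = a$b,
                   elesy = a$elesy)
  if (!is.null(struct$cell)) {
    cl <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                  struct$cell[1], struct$cell[2], struct$cell[3],
                  struct$cell[4], struct$cell[5], struct$cell[6],
                  struct$spacegroup %||% "P 1")
    body <- readLines(path, warn = FALSE)
    writeLines(c(cl, body), path)
  }
  invisible(path)
}

#' Column-name dialect for crosslink tables
#'
#' Maps the package's field names to the column headers of a tab-separated
#' crosslink identification table. The default matches xQuest-style
#' exports; pass a modified map for other layouts.
#'
#' @param ... overrides, e.g. `id_score = "ld.Score"`.
#' @return Named character vector (field -> column header).
#' @export
xquest_dialect <- function(...) {
  d <- c(protein_a = "Protein1", protein_b = "Protein2",
         pos_a = "AbsPos1", pos_b = "AbsPos2",
         peptide_a = "Peptide1", peptide_b = "Peptide2",
         id_score = "Id-Score", fdr = "FDR",
         replicate = "Replicate", charge = "Charge")
  ov <- c(...)
  d[names(ov)] <- ov
  d
}

#' Read a crosslink identification table
#'
#' @param path tab-separated file with one identified cross-linked peptide
#'   pair per row.
#' @param dialect column-name map from [xquest_dialect()].
#' @return Data frame with columns `protein_a`, `pos_a`, `peptide_a`,
#'   `protein_b`, `pos_b`, `peptide_b`, `id_score`, `fdr`, `replicate`,
#'   `charge`.
#' @export
read_xlink_table <- function(path, dialect = xquest_dialect()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  mandatory <- c("protein_a", "protein_b", "pos_a", "pos_b", "id_score", "fdr")
  for (f in mandatory) {
    if (!(dialect[[f]] %in% names(tab)))
      stopf("crosslink table is missing mandatory column '%s' (field %s)",
            dialect[[f]], f)
  }
  get <- function(f, default = NA) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(tab)) tab[[col]] else default
  }
  out <- data.frame(
    protein_a = as.character(get("protein_a")),
    pos_a = as.integer(get("pos_a")),
    peptide_a = as.character(get("peptide_a", "")),
    protein_b = as.character(get("protein_b")),
    pos_b = as.integer(get("pos_b")),
    peptide_b = as.character(get("peptide_b", "")),
    id_score = as.numeric(get("id_score")),
    fdr = as.numeric(get("fdr")),
    replicate = as.integer(get("replicate", 1L)),
    charge = as.integer(get("charge", NA_integer_)),
    stringsAsFactors = FALSE)
  if (any(out$pos_a < 1, na.rm = TRUE) || any(out$pos_b < 1, na.rm = TRUE))
    stopf("crosslink positions must be >= 1")
  if (any(!is.finite(out$id_score)))
    stopf("non-finite id_score in crosslink table")
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE))
    stopf("fdr must lie in [0, 1]")
  out
}

#' Write a crosslink table
#'
#' @param records crosslink records as returned by [read_xlink_table()].
#' @param path output file.
#' @param dialect column-name map from [xquest_dialect()].
#' @return `path`, invisibly.
#' @export
write_xlink_table <- function(records, path, dialect = xquest_dialect()) {
  fields <- intersect(names(dialect), names(records))
  tab <- records[, fields, drop = FALSE]
  names(tab) <- dialect[fields]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a position-specific scoring matrix
#'
#' Whitespace-delimited table: a header row naming the 20 amino acids,
#' then one row of 20 nonnegative weights per motif position. Comment
#' lines start with `#`; a `# anchor_offset: N` comment records the
#' window index of the position-1 anchor.
#'
#' @param path matrix file.
#' @return A [motif_matrix()] object.
#' @export
read_motif_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  anchor <- 1L
  am <- grep("^#\\s*anchor_offset:", lines, value = TRUE)
  if (length(am) > 0)
    anchor <- as.integer(sub("^#\\s*anchor_offset:\\s*", "", am[1]))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2) stopf("matrix file %s has no data rows", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  aa_cols <- match(AA1, header)
  if (any(is.na(aa_cols)))
    stopf("matrix header must name all 20 amino acids; missing: %s",
          paste(AA1[is.na(aa_cols)], collapse = ", "))
  rows <- lapply(seq_along(lines[-1]), function(i) {
    f <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    w <- suppressWarnings(as.numeric(f[aa_cols]))
    if (length(f) < max(aa_cols) || any(is.na(w)))
      stopf("matrix row %d does not provide 20 numeric weights", i)
    w
  })
  weights <- do.call(rbind, rows)
  colnames(weights) <- AA1
  motif_matrix(weights, anchor_offset = anchor)
}

#' Write a position-specific scoring matrix
#'
#' @param matrix a [motif_matrix()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# anchor_offset: %d", matrix$anchor_offset), con)
  writeLines(paste(c("pos", AA1), collapse = "\t"), con)
  for (i in seq_len(matrix$width)) {
    writeLines(paste(c(i, format(matrix$weights[i, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a concentration-response curve
#'
#' CSV with columns `x` (concentration, strictly positive), `y`
#' (response) and optionally `y_err` (per-point s.e.m.). Rows are sorted
#' by ascending concentration.
#'
#' @param path CSV file.
#' @return Data frame with columns `x`, `y` and optionally `y_err`.
#' @export
read_binding_curve <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(tab)))
    stopf("binding curve CSV must have columns x and y")
  if (any(!is.finite(tab$x)) || any(tab$x <= 0))
    stopf("concentrations x must be finite and strictly positive")
  tab[order(tab$x), , drop = FALSE]
}

#' Write an analysis report as JSON
#'
#' @param report a named list.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
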