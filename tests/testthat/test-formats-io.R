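test_that("FASTA reading validates, uppercases and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 AKAP79 CaM-binding peptide", "GAWASLKRLVTRRKRS"), f)
  rec <- read_fasta(f)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$id, "p1")
  expect_equal(nchar(rec$seq), 16)
  expect_equal(rec$seq, "GAWASLKRLVTRRKRS")

  # lowercase input is uppercased
  writeLines(c(">p2", "gawaslKRL"), f)
  expect_equal(read_fasta(f)$seq, "GAWASLKRL")

  # two records round-trip byte-identically at 60-column wrap
  f2 <- withr::local_tempfile(fileext = ".fasta")
  f3 <- withr::local_tempfile(fileext = ".fasta")
  set.seed(42)
  recs <- data.frame(
    id = c("alpha", "beta"), desc = c("first", ""),
    seq = c(paste(sample(c("A", "C", "G", "W"), 150, TRUE), collapse = ""),
            "MKV"))
  write_fasta(recs, f2)
  back <- read_fasta(f2)
  expect_equal(back$seq, recs$seq)
  write_fasta(back, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("FASTA reader rejects empty files and illegal letters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">bad", "GAWBSL"), f)
  expect_error(read_fasta(f), "'B'.*position 4")
})

test_that("PDB structures read with cell, altlocs resolved, and round-trip", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atoms <- mini_atoms()
  write_mini_pdb(f, atoms, cell = c(76.46, 76.46, 128.99, 90, 90, 90),
                 spacegroup = "P 42 21 2")
  s <- read_structure(f)
  expect_s3_class(s, "struct3d")
  expect_equal(nrow(s$atoms), 4)
  expect_equal(s$cell[1], 76.46)
  expect_equal(s$spacegroup, "P 42 21 2")
  expect_equal(s$atoms$x[2], 1.458)

  # single-atom fixture
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f1, atoms[2, , drop = FALSE])
  s1 <- read_structure(f1)
  expect_equal(nrow(s1$atoms), 1)
  expect_equal(as.numeric(s1$atoms[1, c("x", "y", "z")]), c(1.458, 0, 0))

  # round-trip preserves atom count and coordinates to 3 decimals
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f2)
  s2 <- read_structure(f2)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(s2$cell, s$cell)
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atoms <- rbind(mini_atoms()[1:2, ], mini_atoms()[2, ])
  atoms$alt <- c("", "A", "B")
  atoms$occ <- c(1, 0.4, 0.6)
  atoms$x[3] <- 9.99
  write_mini_pdb(f, atoms)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(ca$x, 9.99)  # occupancy 0.6 wins
})

test_that("the same content in PDB and mmCIF dialects parses identically", {
  atoms <- mini_atoms()
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_mini_pdb(fp, atoms)
  write_mini_cif(fc, atoms)
  sp <- read_structure(fp)
  sc <- read_structure(fc)
  expect_equal(nrow(sp$atoms), nrow(sc$atoms))
  expect_equal(as.matrix(sp$atoms[, c("x", "y", "z")]),
               as.matrix(sc$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  expect_equal(sp$atoms$resno, sc$atoms$resno)
  expect_equal(sp$cell[1:3], sc$cell[1:3])
})

test_that("crosslink tables read with the dialect map and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    Protein1 = c("CaM", "AKAP79", "AKAP79"),
    Protein2 = c("AKAP79", "AKAP79", "AKAP79"),
    AbsPos1 = c(94, 41, 83), AbsPos2 = c(99, 177, 83),
    Peptide1 = c("AKDTDSEEEIR", "LSNK", "MK"),
    Peptide2 = c("NYKK", "TTR", "MK"),
    `Id-Score` = c(31.5, 28.0, 22.1), FDR = c(0.04, 0.01, 0.0),
    Replicate = c(1, 2, 3), Charge = c(3, 4, 3), check.names = FALSE)
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_xlink_table(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$pos_a, c(94L, 41L, 83L))
  expect_equal(rec$fdr[1], 0.04)

  # missing mandatory column is named in the error
  bad <- tab[, setdiff(names(tab), "FDR")]
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_xlink_table(f), "FDR")

  # custom dialect
  names(tab) <- c("protA", "protB", "siteA", "siteB", "pepA", "pepB",
                  "score", "fdr", "rep", "z")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- xquest_dialect(protein_a = "protA", protein_b = "protB",
                      pos_a = "siteA", pos_b = "siteB", peptide_a = "pepA",
                      peptide_b = "pepB", id_score = "score", fdr = "fdr",
                      replicate = "rep", charge = "z")
  expect_equal(read_xlink_table(f, d)$pos_b, c(99L, 177L, 83L))
})

test_that("generated crosslink tables round-trip losslessly through TSV", {
  xt <- make_xlink_table(xlink_spec(n_interlink = 12, n_intralink_a = 6,
                                    n_intralink_b = 3, n_symmetric = 2,
                                    hotspot = list(partner_pos = 94,
                                                   targets = c("99" = 6)),
                                    n_below = 5, seed = 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_xlink_table(xt$records, f)
  back <- read_xlink_table(f)
  expect_equal(back, xt$records, tolerance = 1e-12)
})

test_that("motif matrix files round-trip exactly and are validated", {
  m <- build_default_matrix()
  expect_gte(m$width, 8)
  f <- withr::local_tempfile(fileext = ".txt")
  write_motif_matrix(m, f)
  m2 <- read_motif_matrix(f)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$anchor_offset, m$anchor_offset)

  # all-equal weights score every window identically
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  flat <- motif_matrix(matrix(1, 4, 20, dimnames = list(NULL, aa)))
  expect_equal(score_window(flat, "AAAA"), score_window(flat, "WKRV"))

  # row with the wrong number of weights errors
  lines <- readLines(f)
  lines[4] <- paste(strsplit(lines[4], "\t")[[1]][1:10], collapse = "\t")
  writeLines(lines, f)
  expect_error(read_motif_matrix(f), "20")
})

test_that("binding curve CSV is validated and sorted", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = c(100, 1, 10), y = c(0.2, 0.9, 0.5)),
                   f, row.names = FALSE)
  cv <- read_binding_curve(f)
  expect_equal(cv$x, c(1, 10, 100))
  utils::write.csv(data.frame(x = c(-1, 2), y = c(1, 2)), f,
                   row.names = FALSE)
  expect_error(read_binding_curve(f), "positive")
})
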