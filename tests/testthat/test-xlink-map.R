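test_that("confidence filtering uses strict boundaries on score and FDR", {
  recs <- rbind(
    xl_rec("CaM", 94, "AKAP79", 99, id_score = 20.0, fdr = 0.01),
    xl_rec("CaM", 94, "AKAP79", 96, id_score = 35, fdr = 0.05),
    xl_rec("CaM", 94, "AKAP79", 90, id_score = 35, fdr = 0.049),
    xl_rec("CaM", 12, "AKAP79", 50, id_score = 20.0001, fdr = 0.0))
  out <- filter_links(recs)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$pos_b), c(50, 90))
})

test_that("deduplication collapses charge states but keeps peptide forms
           and replicates distinct", {
  base <- xl_rec("CaM", 94, "AKAP79", 99, peptide_a = "AKDTDSEEEIR",
                 peptide_b = "NYKK")
  # same peptide pair, same replicate, charges 3+ and 4+ -> one detection
  two_charges <- rbind(base, transform(base, charge = 4L))
  expect_equal(nrow(deduplicate_links(two_charges)), 1)

  # two peptide forms of different length -> two detections
  two_forms <- rbind(base, transform(base, peptide_b = "NYKKLR"))
  expect_equal(nrow(deduplicate_links(two_forms)), 2)

  # same identification in two biological replicates -> two detections
  two_reps <- rbind(base, transform(base, replicate = 2L))
  expect_equal(nrow(deduplicate_links(two_reps)), 2)

  # swapped A/B sides are the same link
  swapped <- rbind(base, data.frame(
    protein_a = base$protein_b, pos_a = base$pos_b,
    peptide_a = base$peptide_b, protein_b = base$protein_a,
    pos_b = base$pos_a, peptide_b = base$peptide_a,
    id_score = base$id_score, fdr = base$fdr,
    replicate = base$replicate, charge = base$charge))
  expect_equal(nrow(deduplicate_links(swapped)), 1)

  # idempotence and empty input
  expect_equal(deduplicate_links(deduplicate_links(two_forms)),
               deduplicate_links(two_forms))
  expect_equal(nrow(deduplicate_links(base[0, ])), 0)
})

test_that("links classify into interlink, intralink and symmetric dimer", {
  recs <- rbind(
    xl_rec("CaM", 94, "AKAP79", 99),
    xl_rec("AKAP79", 83, "AKAP79", 83),
    xl_rec("AKAP79", 41, "AKAP79", 177))
  map <- classify_links(recs, c("AKAP79", "CaM"))
  cat_of <- function(pa, pb) {
    map$category[map$pos_a == pa & map$pos_b == pb]
  }
  expect_equal(unname(cat_of(99, 94)), "interlink")
  expect_equal(unname(cat_of(83, 83)), "symmetric_dimer")
  expect_equal(unname(cat_of(41, 177)), "intralink")
  expect_error(classify_links(xl_rec("PKA", 1, "CaM", 2),
                              c("AKAP79", "CaM")), "PKA")
})

test_that("link frequency ranks by count with position tie-breaks", {
  recs <- rbind(
    do.call(rbind, replicate(16, xl_rec("AKAP79", 99, "CaM", 94),
                             simplify = FALSE)),
    do.call(rbind, replicate(7, xl_rec("AKAP79", 96, "CaM", 94),
                             simplify = FALSE)),
    do.call(rbind, replicate(4, xl_rec("AKAP79", 90, "CaM", 94),
                             simplify = FALSE)))
  recs$peptide_a <- paste0(recs$peptide_a, seq_len(nrow(recs)))  # unique forms
  map <- classify_links(recs, c("AKAP79", "CaM"))
  fr <- link_frequency(map, "CaM", 94)
  expect_equal(fr$count, c(16, 7, 4))
  expect_equal(fr$pos_a, c(99, 96, 90))

  # ties order by ascending position
  ties <- rbind(xl_rec("AKAP79", 120, "CaM", 94),
                xl_rec("AKAP79", 90, "CaM", 94))
  mt <- classify_links(ties, c("AKAP79", "CaM"))
  ft <- link_frequency(mt, "CaM", 94)
  expect_equal(ft$pos_a, c(90, 120))

  # empty map
  empty <- classify_links(recs[0, ], c("AKAP79", "CaM"))
  expect_equal(nrow(link_frequency(empty)), 0)
})

test_that("triangulation reproduces hand-computed weighted means", {
  mk <- function(counts) {
    rows <- do.call(rbind, lapply(names(counts), function(p) {
      do.call(rbind, replicate(counts[[p]],
                               xl_rec("AKAP79", as.integer(p), "CaM", 94),
                               simplify = FALSE))
    }))
    rows$peptide_a <- paste0(rows$peptide_a, seq_len(nrow(rows)))
    classify_links(rows, c("AKAP79", "CaM"))
  }
  tri <- triangulate_site(mk(c("90" = 4, "96" = 7, "99" = 16)), "AKAP79",
                          seed = 1)
  expect_equal(tri$position, 2616 / 27, tolerance = 1e-9)
  expect_equal(tri$n_detections, 27)
  expect_true(tri$ci[1] >= 90 && tri$ci[2] <= 99)

  # single link: exact position, zero-width CI
  t1 <- triangulate_site(mk(c("99" = 1)), "AKAP79", seed = 1)
  expect_equal(t1$position, 99)
  expect_equal(unname(diff(t1$ci)), 0)

  # uniform counts: symmetric midpoint
  t2 <- triangulate_site(mk(c("90" = 3, "99" = 3)), "AKAP79", seed = 1)
  expect_equal(t2$position, 94.5)

  # scaling all counts leaves the estimate unchanged
  t4 <- triangulate_site(mk(c("90" = 8, "96" = 14, "99" = 32)), "AKAP79",
                         seed = 1)
  expect_equal(t4$position, tri$position)

  # no interlinks -> error
  sym <- classify_links(xl_rec("AKAP79", 83, "AKAP79", 83),
                        c("AKAP79", "CaM"))
  expect_error(triangulate_site(sym, "AKAP79"), "interlink")
})

test_that("count summaries conserve totals on seeded synthetic tables", {
  for (seed in c(1, 7, 23)) {
    spec <- xlink_spec(n_interlink = 20, n_intralink_a = 12,
                       n_intralink_b = 5, n_symmetric = 3, n_below = 10,
                       hotspot = list(partner_pos = 94,
                                      targets = c("90" = 2, "96" = 3,
                                                  "99" = 6)),
                       seed = seed)
    xt <- make_xlink_table(spec)
    map <- classify_links(deduplicate_links(filter_links(xt$records)),
                          c("AKAP79", "CaM"))
    cs <- count_summary(map)
    expect_equal(cs$total, cs$n_interlink + cs$n_intralink_a +
                   cs$n_intralink_b + cs$n_symmetric)
    expect_equal(cs$n_interlink, 20)
    expect_equal(cs$n_intralink_a, 12)
    expect_equal(cs$n_intralink_b, 5)
    expect_equal(cs$n_symmetric, 3)
  }
})

test_that("hot-spot share reports both detection and pair percentages", {
  xt <- make_xlink_table(xlink_spec(seed = 2))
  map <- classify_links(deduplicate_links(filter_links(xt$records)),
                        c("AKAP79", "CaM"))
  sh <- hotspot_share(map, "CaM", 94)
  expect_equal(sh$pct_detections, 100 * 27 / 47, tolerance = 1e-9)
  expect_true(sh$pct_pairs < sh$pct_detections)
})
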