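test_that("the module grammar parses steps, alternatives and complexes", {
  m <- parse_module("K00001 K00002")
  expect_equal(m$step_count, 2)
  expect_equal(vapply(m$expression$children, `[[`, "", "kind"),
               c("ko", "ko"))

  m2 <- parse_module("(K00001,K00002) K00003")
  expect_equal(m2$step_count, 2)
  expect_equal(m2$expression$children[[1]]$kind, "or")
  expect_true(module_completeness(m2, c("K00002", "K00003"))$detected)

  m3 <- parse_module("K00001+K00002")
  expect_equal(m3$step_count, 1)
  expect_equal(module_completeness(m3, "K00001")$fraction_present, 0)
  expect_equal(module_completeness(m3, c("K00001", "K00002"))$fraction_present,
               1)

  # optional components and gap steps are excluded from the denominator
  m4 <- parse_module("K00001 -K00009 K00003")
  expect_equal(m4$step_count, 2)
  expect_equal(module_completeness(m4, c("K00001", "K00003"))$fraction_present,
               1)
  m5 <- parse_module("K00001 -- K00002")
  expect_equal(m5$step_count, 2)
})

test_that("parse errors carry a position and malformed tokens are rejected", {
  expect_error(parse_module("(K00001 K00002"), "parenthes")
  expect_error(parse_module("K00001)"), "parenthes")
  expect_error(parse_module(""), "empty")
  expect_error(parse_module("K1 K00002"), "malformed KO")
  expect_error(parse_module("K000012"), "malformed KO")
})

test_that("render and reparse round-trips the expression tree", {
  fixtures <- c(
    "K00001 K00002",
    "(K00001,K00002) K00003",
    "K00001+K00002",
    "K00001 -K00009 K00003",
    "K00001+K00002,K00003 K00004",
    "(K00001 K00002) K00003",
    "K00001 -- K00002 -(K00003 K00004)",
    "(K00001,K00002+K00003) K00004+K00005")
  for (def in fixtures) {
    m <- parse_module(def)
    m2 <- parse_module(render_module(m))
    expect_identical(m$expression, m2$expression, info = def)
    expect_identical(m$step_count, m2$step_count, info = def)
  }
})

test_that("a nested serial group is one step requiring full completion", {
  m <- parse_module("(K00001 K00002) K00003")
  expect_equal(m$step_count, 2)
  expect_equal(module_completeness(m, c("K00001", "K00003"))$fraction_present,
               0.5)
  expect_equal(module_completeness(m,
                                   c("K00001", "K00002",
                                     "K00003"))$fraction_present, 1)
})

test_that("exactly half of required steps present is undetected", {
  m <- parse_module("K00001 K00002 K00003 K00004")
  res <- module_completeness(m, c("K00001", "K00002"))
  expect_equal(res$fraction_present, 0.5)
  expect_false(res$detected)
  expect_true(module_completeness(m, c("K00001", "K00002",
                                       "K00003"))$detected)
  expect_equal(module_completeness(m, character(0))$fraction_present, 0)
  expect_equal(module_completeness(m, paste0("K0000", 1:4))$fraction_present,
               1)
})

test_that("completeness is monotone under KO addition", {
  set.seed(55)
  pool <- sprintf("K%05d", sample(1:99999, 2000))
  used <- 0
  for (i in 1:100) {
    def <- random_module_definition(pool[(used + 1):(used + 18)])
    used <- used + 18
    m <- parse_module(def)
    kos <- module_kos <- unique(unlist(regmatches(def,
                                                  gregexpr("K[0-9]{5}", def))))
    small <- sample(kos, size = sample(0:length(kos), 1))
    extra <- sample(setdiff(kos, small),
                    size = sample(0:length(setdiff(kos, small)), 1))
    f_small <- module_completeness(m, small)$fraction_present
    f_large <- module_completeness(m, c(small, extra))$fraction_present
    expect_gte(f_large, f_small)
  }
})

profile_fixture <- function() {
  ann <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    ko = c("K03520", "K03520,K01601", "", ""),
    symbol = c(NA, "coxL", "rbcL", "dsrA"),
    lineage = c("Bacteria;Proteobacteria", "Bacteria;Proteobacteria",
                "Bacteria;Chloroflexi", ""),
    panels = c("", "", "", ""),
    stringsAsFactors = FALSE)
  counts <- matrix(c(7.5, 1, 2, 4, 3, 5, 0.5, 2), 4, 2,
                   dimnames = list(ann$gene_id, c("S1", "S2")))
  list(ann = ann, counts = counts)
}

test_that("marker abundance sums matches by KO first, symbol fallback, once", {
  fx <- profile_fixture()
  ma <- marker_abundance(fx$ann, fx$counts)
  # coxL: gA by KO, gB by KO and symbol (counted once)
  expect_equal(unname(ma["coxL", ]), unname(colSums(fx$counts[c("gA", "gB"), ])))
  # rbcL: gB by KO, gC by symbol fallback
  expect_equal(unname(ma["rbcL", ]), unname(colSums(fx$counts[c("gB", "gC"), ])))
  # dsrA by symbol only
  expect_equal(unname(ma["dsrA", ]), unname(fx$counts["gD", ]))
  # mcrA absent everywhere: explicit zero row, still emitted
  expect_true("mcrA" %in% rownames(ma))
  expect_equal(unname(ma["mcrA", ]), c(0, 0))
  # duplicate marker names (one marker, two categories) rejected
  bad_map <- rbind(default_marker_map(), default_marker_map()[1, ])
  expect_error(marker_abundance(fx$ann, fx$counts, bad_map),
               "more than one category")
})

test_that("marker matrices are linear in the normalized counts", {
  fx <- profile_fixture()
  ma1 <- marker_abundance(fx$ann, fx$counts)
  ma3 <- marker_abundance(fx$ann, fx$counts * 3)
  expect_equal(ma3, ma1 * 3)
})

test_that("hydrogenase profiles keep the full group index", {
  fx <- profile_fixture()
  ann <- fx$ann
  ann$symbol <- c("hndD", "hoxH", NA, NA)
  ann$ko <- ""
  hp <- hydrogenase_profile(ann, fx$counts)
  expect_equal(rownames(hp), default_hydrogenase_map()$group_label)
  expect_equal(unname(hp["FeFe-A3", ]), unname(fx$counts["gA", ]))
  expect_equal(unname(hp["NiFe-3d", ]), unname(fx$counts["gB", ]))
  expect_equal(sum(hp[c("FeFe-A", "FeFe-B", "NiFe-1"), ]), 0)
  # empty annotation: all-zero matrix with full index
  hp0 <- hydrogenase_profile(fx$ann[0, ], fx$counts)
  expect_equal(dim(hp0), c(10, 2))
  expect_true(all(hp0 == 0))
})

test_that("lineage completion pools KOs per lineage at the chosen rank", {
  mods <- data.frame(module_id = "M1",
                     definition = "K00001 K00002 K00003 K00004")
  ann <- data.frame(
    gene_id = paste0("g", 1:5),
    ko = c("K00001", "K00002,K00003", "K00001", "K00001", ""),
    symbol = NA,
    lineage = c("Bacteria;Nitrospirae", "Bacteria;Nitrospirae",
                "Bacteria;Chloroflexi", "Archaea;Thaumarchaeota", ""),
    stringsAsFactors = FALSE)
  cm <- lineage_completion_matrix(ann, mods, rank = "phylum")
  cm <- cm[order(cm$lineage), ]
  expect_equal(cm$fraction_present[cm$lineage == "Nitrospirae"], 0.75)
  expect_true(cm$detected[cm$lineage == "Nitrospirae"])
  expect_equal(cm$fraction_present[cm$lineage == "Chloroflexi"], 0.25)
  expect_equal(cm$fraction_present[cm$lineage == "unclassified"], 0)
  # two lineages with identical KO sets get identical rows
  ann2 <- ann[c(3, 3), ]
  ann2$gene_id <- c("x1", "x2")
  ann2$lineage <- c("Bacteria;A1", "Bacteria;A2")
  cm2 <- lineage_completion_matrix(ann2, mods, rank = "phylum")
  expect_equal(cm2$fraction_present[1], cm2$fraction_present[2])
})

test_that("lineage abundance columns sum to 100 in every mode", {
  prog <- data.frame(lineage = c("Proteobacteria", "Chloroflexi"),
                     module_id = "MS0001", fraction = c(1, 0.5))
  sim <- simulate_annotations(prog, sample_ids = c("S1", "S2"),
                              lineage_proportions = c(Proteobacteria = 0.6,
                                                      Chloroflexi = 0.4))
  for (mode in c("all_genes", "scg12", "scg40", "rrna16s")) {
    la <- lineage_abundance(sim$annotations, sim$abundance, mode = mode)
    expect_equal(unname(colSums(la)), rep(100, 2), tolerance = 1e-9)
  }
  la <- lineage_abundance(sim$annotations, sim$abundance, mode = "scg12")
  expect_equal(la["Proteobacteria", "S1"], 60)
  expect_equal(la["Chloroflexi", "S1"], 40)
  # all genes from one phylum -> 100%
  one <- sim$annotations[grepl("Proteobacteria", sim$annotations$lineage), ]
  la1 <- lineage_abundance(one, sim$abundance, mode = "all_genes")
  expect_equal(unname(la1["Proteobacteria", ]), c(100, 100))
  expect_error(lineage_abundance(sim$annotations[0, ], sim$abundance,
                                 mode = "scg12"), "panel")
})
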