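toy_counts <- function() {
  sortseq_counts(data.frame(design_id = c("A", "WT"),
                            u = c(100L, 100L),
                            d = c(10L, 50L),
                            b = c(90L, 50L),
                            stringsAsFactors = FALSE),
                 wt_id = "WT")
}

test_that("read pairs merge by quality with forward-wins ties", {
  # zero-length overlap: plain concatenation at the offset
  expect_identical(merge_read_pair("ACGT", "IIII", "TTAA", "IIII",
                                   offset = 4), "ACGTTTAA")
  # overlap: higher quality wins; Phred+33 ('?' = Q30, '5' = Q20)
  expect_identical(merge_read_pair("AA", "I?", "CC", "5I", offset = 1),
                   "AAC")
  expect_identical(merge_read_pair("AA", "I5", "CC", "?I", offset = 1),
                   "ACC")
  # equal quality keeps the forward base
  expect_identical(merge_read_pair("AA", "II", "CC", "II", offset = 1),
                   "AAC")
  expect_error(merge_read_pair("AAAA", "IIII", "CC", "II", offset = 5),
               "gap")
  expect_error(merge_read_pair("AAAA", "IIII", "CC", "II", offset = -1),
               "negative")

  # random pairs against a position-by-position oracle
  set.seed(140)
  for (i in 1:50) {
    lf <- sample(6:12, 1); lr <- sample(6:12, 1)
    off <- sample(0:lf, 1)
    fwd <- paste(sample(c("A", "C", "G", "T"), lf, TRUE), collapse = "")
    rev <- paste(sample(c("A", "C", "G", "T"), lr, TRUE), collapse = "")
    qf <- sample(0:40, lf, TRUE); qr <- sample(0:40, lr, TRUE)
    total <- max(lf, off + lr)
    base <- rep("", total); qual <- rep(-1L, total)
    base[1:lf] <- strsplit(fwd, "")[[1]]; qual[1:lf] <- qf
    for (j in 1:lr) {
      pos <- off + j
      if (qr[j] > qual[pos]) {
        base[pos] <- strsplit(rev, "")[[1]][j]
        qual[pos] <- qr[j]
      }
    }
    expect_identical(merge_read_pair(fwd, qf, rev, qr, offset = off),
                     paste(base, collapse = ""))
  }
})

test_that("exact-match counting assigns nothing to near-misses", {
  lib <- c(A = "ACGTACGT", B = "ACGTACGA", Bsyn = "ACGAACGA")
  reads <- c("ACGTACGT", "ACGTACGT", "ACGTACGA", "ACGTACGC", "ACGAACGA")
  counts <- count_exact_matches(reads, lib)
  expect_identical(unname(counts["A"]), 2L)
  expect_identical(unname(counts["B"]), 1L)
  expect_identical(unname(counts["Bsyn"]), 1L)   # synonymous control: own id
  expect_identical(attr(counts, "unassigned"), 1L)
  expect_error(count_exact_matches(reads, c(A = "ACGT", B = "ACGT")),
               "duplicate")
})

test_that("the minimum-count filter drops underrepresented designs only", {
  cts <- sortseq_counts(data.frame(design_id = c("WT", "x", "y", "z"),
                                   u = c(50L, 9L, 10L, 200L),
                                   d = c(5L, 5L, 5L, 5L),
                                   b = c(5L, 5L, 5L, 5L)),
                        wt_id = "WT")
  kept <- filter_min_count(cts, min_count = 10)
  expect_setequal(kept$design_id, c("WT", "y", "z"))     # 9 out, 10 in
  all_ok <- filter_min_count(cts, min_count = 5)
  expect_identical(nrow(all_ok), 4L)
  low_wt <- sortseq_counts(data.frame(design_id = c("WT", "x"),
                                      u = c(3L, 50L), d = c(1L, 5L),
                                      b = c(1L, 5L)), wt_id = "WT")
  expect_error(filter_min_count(low_wt), "wild type")
})

test_that("enrichment scores match hand-evaluated log-ratios", {
  et <- enrichment_scores(toy_counts())
  wt_row <- et$design_id == "WT"
  expect_identical(et$e_bind[wt_row], 0)
  expect_identical(et$e_disp[wt_row], 0)
  # hand arithmetic: totals u=200, d=60, b=140
  # pA = (.5, 1/6, 9/14), pwt = (.5, 5/6, 5/14)
  # e_bind(A) = log10((9/14)/(1/6)) - log10((5/14)/(5/6)) = log10(9)
  expect_equal(et$e_bind[!wt_row], log10(9))
  # e_disp(A) = log10(0.904762/0.5 / (1.095238/0.5))
  expect_equal(et$e_disp[!wt_row],
               log10((0.6 * 9 / 14 + 0.4 / 6) / (0.6 * 5 / 14 + 0.4 * 5 / 6)),
               tolerance = 1e-12)
  expect_false(any(et$pseudocount))
})

test_that("designs with identical proportions to wild type score zero", {
  cts <- sortseq_counts(data.frame(design_id = c("twin", "WT", "other"),
                                   u = c(40L, 40L, 20L),
                                   d = c(30L, 30L, 40L),
                                   b = c(25L, 25L, 50L)), wt_id = "WT")
  et <- enrichment_scores(cts)
  expect_equal(et$e_bind[et$design_id == "twin"], 0)
  expect_equal(et$e_disp[et$design_id == "twin"], 0)
})

test_that("zero sorted counts are pseudocount-rescued and flagged", {
  cts <- sortseq_counts(data.frame(design_id = c("dead", "WT"),
                                   u = c(100L, 100L),
                                   d = c(50L, 50L),
                                   b = c(0L, 50L)), wt_id = "WT")
  et <- enrichment_scores(cts)
  expect_true(et$pseudocount[et$design_id == "dead"])
  expect_true(is.finite(et$e_bind[et$design_id == "dead"]))
  expect_false(et$pseudocount[et$design_id == "WT"])
})

test_that("scores are invariant to uniform count scaling per population", {
  cts <- toy_counts()
  scaled <- sortseq_counts(data.frame(design_id = cts$design_id,
                                      u = cts$u * 7L, d = cts$d * 3L,
                                      b = cts$b * 11L), wt_id = "WT")
  expect_equal(enrichment_scores(scaled)$e_bind,
               enrichment_scores(cts)$e_bind)
  expect_equal(enrichment_scores(scaled)$e_disp,
               enrichment_scores(cts)$e_disp)
})

test_that("population enrichment follows its log-ratio identity", {
  cts <- sortseq_counts(data.frame(design_id = c("A", "WT"),
                                   u = c(50L, 50L),
                                   d = c(30L, 30L),
                                   b = c(70L, 40L),
                                   h = c(80L, 40L)), wt_id = "WT")
  eh <- population_enrichment(cts, "h")
  expect_identical(eh$e_x[eh$design_id == "WT"], 0)
  # A is exactly twice as enriched as wild type in h relative to u
  expect_equal(eh$e_x[eh$design_id == "A"], log10(2))
  # algebraic consistency: e_b - e_d over u equals the binding score
  eb <- population_enrichment(cts, "b")$e_x
  ed <- population_enrichment(cts, "d")$e_x
  expect_equal(eb - ed, enrichment_scores(cts)$e_bind)
  expect_error(population_enrichment(cts, "l"), "not present")
})

test_that("quadrant classification respects the >= threshold rule", {
  cts <- toy_counts()
  et <- enrichment_scores(cts)
  cls <- classify_designs(et, thresholds = list(display = 0, bind = 0))
  # wild type sits on both thresholds: boundary counts as positive
  expect_identical(as.character(cls$category[cls$design_id == "WT"]),
                   "display_bind")
  low <- et
  low$e_bind <- c(-3, 0)
  low$e_disp <- c(-2, 0)
  cls2 <- classify_designs(low, thresholds = list(display = 0, bind = 0))
  expect_identical(as.character(cls2$category[cls2$design_id == "A"]),
                   "inactive")
  expect_error(classify_designs(et), "thresholds or calibration")
})

test_that("simulated screens recover the designed truth", {
  set.seed(150)
  n <- 120
  ids <- c("WT", paste0("d", seq_len(n - 1)))
  displays <- c(TRUE, runif(n - 1) < 0.6)
  binds <- c(TRUE, runif(n - 1) < 0.5) & displays
  disp_p <- ifelse(displays, runif(n, 0.6, 0.95), runif(n, 0.005, 0.03))
  bind_p <- ifelse(binds, runif(n, 0.5, 0.95), runif(n, 0.001, 0.02))
  cts <- simulate_sortseq_counts(ids, disp_p, bind_p, depth = 1e6, seed = 8)
  et <- enrichment_scores(filter_min_count(cts))
  cal <- data.frame(e_disp = et$e_disp, e_bind = et$e_bind,
                    displays = displays, binds = binds)
  cls <- classify_designs(et, calibration = cal)
  truth <- ifelse(displays & binds, "display_bind",
           ifelse(displays, "display_only",
           ifelse(binds, "bind_no_display", "inactive")))
  accuracy <- mean(as.character(cls$category) == truth)
  expect_gte(accuracy, 0.95)
})

test_that("replicates and synonymous controls agree in simulation", {
  set.seed(151)
  n <- 60
  ids <- c("WT", paste0("d", seq_len(n - 1)))
  disp_p <- c(0.9, runif(n - 1, 0.2, 0.95))
  bind_p <- c(0.7, runif(n - 1, 0.05, 0.95))
  e1 <- enrichment_scores(filter_min_count(
    simulate_sortseq_counts(ids, disp_p, bind_p, depth = 1e6, seed = 21)))
  e2 <- enrichment_scores(filter_min_count(
    simulate_sortseq_counts(ids, disp_p, bind_p, depth = 1e6, seed = 22)))
  shared <- intersect(e1$design_id, e2$design_id)
  r <- cor(e1$e_bind[match(shared, e1$design_id)],
           e2$e_bind[match(shared, e2$design_id)])
  expect_gt(r, 0.9)
  # synonymous controls: same protein-level truth, independent counts
  syn_ids <- c("WT", paste0(rep(paste0("p", 1:20), each = 2), c("_a", "_b")))
  syn_disp <- c(0.9, rep(runif(20, 0.3, 0.95), each = 2))
  syn_bind <- c(0.7, rep(runif(20, 0.1, 0.95), each = 2))
  es <- enrichment_scores(filter_min_count(
    simulate_sortseq_counts(syn_ids, syn_disp, syn_bind, depth = 1e6,
                            seed = 23)))
  a <- es$e_bind[grepl("_a$", es$design_id)]
  b <- es$e_bind[grepl("_b$", es$design_id)]
  expect_gt(cor(a, b), 0.95)
  expect_lt(median(abs(a - b)), 0.05)
})

test_that("calibration thresholds sit midway between class means", {
  vals <- c(0.1, 0.3, 1.0, 1.2, 2.4, 2.6)
  cls <- rep(c("low", "wt", "high"), each = 2)
  bounds <- calibration_thresholds(vals, cls)
  expect_equal(unname(bounds), c((0.2 + 1.1) / 2, (1.1 + 2.5) / 2),
               ignore_attr = TRUE)
  lab <- classify_bins(c(0, 1.1, 3), bounds)
  expect_identical(as.character(lab), c("low", "wt", "high"))
})

test_that("the Hill fit recovers KD and Bmax from clean titrations", {
  conc <- c(0.1, 0.5, 1, 3, 10, 30, 100, 300)
  truth <- function(c_) 2 * c_ / (15 + c_)
  fit <- fit_hill(conc, truth(conc))
  expect_equal(fit$kd, 15, tolerance = 1e-6)
  expect_equal(fit$bmax, 2, tolerance = 1e-6)
  # analytic midpoint: the fitted curve passes through Bmax/2 at c = KD
  expect_equal(fit$bmax * fit$kd / (fit$kd + fit$kd), fit$bmax / 2)
  # degenerate all-zero titration
  flat <- fit_hill(conc, rep(0, 8))
  expect_true(flat$degenerate)
  expect_identical(flat$bmax, 0)
  expect_true(is.na(flat$kd))
  expect_error(fit_hill(c(1, 2), c(0.1, 0.2)), "length")
  expect_error(fit_hill(conc, rep(-1, 8)), "non-negative")
})
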