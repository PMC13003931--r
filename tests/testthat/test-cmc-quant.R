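test_that("read_fastq is strict and order-preserving", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "GGCC", "+", "JJJJ"), fq)
  reads <- read_fastq(fq)
  expect_identical(reads$read_id, c("r1", "r2"))
  expect_identical(reads$sequence, c("ACGT", "GGCC"))

  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_identical(nrow(read_fastq(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)
  expect_error(read_fastq(bad), "length mismatch")

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT"), trunc)
  expect_error(read_fastq(trunc), "truncated")

  # round trip through write_fastq
  rt <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, rt)
  expect_identical(read_fastq(rt), reads)
})

test_that("extract_umi slices by offset and rejects short reads", {
  reads <- tibble::tibble(read_id = "r1",
                          sequence = paste0("ACGTACGTAC", "TTTGGG"))
  got <- extract_umi(reads, umi_length = 10, umi_offset = 0)
  expect_identical(got$umi, "ACGTACGTAC")
  expect_identical(got$payload, "TTTGGG")

  # offset 2: first 2 bases stay at the payload head
  off <- extract_umi(tibble::tibble(read_id = "r1",
                                    sequence = "GGACGTACGTACTTT"),
                     umi_length = 10, umi_offset = 2)
  expect_identical(off$umi, "ACGTACGTAC")
  expect_identical(off$payload, "GGTTT")

  expect_error(extract_umi(tibble::tibble(read_id = "tiny",
                                          sequence = "ACGTACGTA"),
                           umi_length = 10),
               "too short")
})

test_that("collapse_by_umi keeps first occurrences in order and is idempotent", {
  reads <- tibble::tibble(read_id = paste0("r", 1:4),
                          sequence = "X",
                          umi = c("A", "B", "A", "C"))
  got <- collapse_by_umi(reads)
  expect_identical(got$read_id, c("r1", "r2", "r4"))

  distinct <- tibble::tibble(read_id = paste0("r", 1:5), sequence = "X",
                             umi = letters[1:5])
  expect_identical(collapse_by_umi(distinct), distinct)

  # brute-force oracle equivalence + idempotence on random read sets
  withr::with_seed(91, {
    for (rep in 1:5) {
      rnd <- tibble::tibble(
        read_id = sprintf("r%d", 1:1000),
        sequence = "X",
        umi = int_to_umi(sample.int(400, 1000, replace = TRUE)))
      got <- collapse_by_umi(rnd)
      expect_identical(got, brute_force_collapse(rnd))
      expect_identical(collapse_by_umi(got), got)
    }
  })
})

test_that("match_anchors requires perfect anchors and bounded gaps", {
  tg <- test_target()
  p2 <- paste0("CC", tg$anchor_up, "GA", tg$anchor_down, "AA")
  p3 <- paste0(tg$anchor_up, "GTG", tg$anchor_down)
  m <- match_anchors(c(p2, p3), tg)
  expect_identical(m$gap_length, c(2L, 3L))
  expect_identical(m$gap_sequence[2], "GTG")
  expect_identical(m$orientation, c("sense", "sense"))

  # one substitution in an anchor disqualifies the read
  mut <- sub("^C", "A", tg$anchor_up)
  bad <- match_anchors(paste0(mut, "GTG", tg$anchor_down), tg)
  expect_false(bad$matched)

  # gaps above max_gap are not locus matches
  wide <- paste0(tg$anchor_up, strrep("A", 11), tg$anchor_down)
  expect_false(match_anchors(wide, tg, max_gap = 10)$matched)
  expect_true(match_anchors(wide, tg, max_gap = 11)$matched)

  # reverse-complement reads match with sense-orientation gap sequence
  rc <- match_anchors(revcomp_chr(p3), tg)
  expect_true(rc$matched)
  expect_identical(rc$orientation, "revcomp")
  expect_identical(rc$gap_sequence, "GTG")
})

test_that("count_locus partitions anchor-matched reads by gap class", {
  tg <- test_target()
  payloads <- c(rep(paste0(tg$anchor_up, "TG", tg$anchor_down), 4),
                rep(paste0(tg$anchor_up, "TTG", tg$anchor_down), 5),
                paste0(tg$anchor_up, "TGG", tg$anchor_down))
  reads <- extract_umi(reads_from_payloads(payloads))
  counts <- count_locus(reads, tg)
  expect_identical(counts$n_anchor_matched, 10L)
  expect_identical(c(counts$n_del, counts$n_ret_T, counts$n_ret_nonT,
                     counts$n_other_gap), c(4L, 5L, 1L, 0L))

  # orientation invariance: reverse-complementing every read leaves counts
  # unchanged (UMI part is irrelevant to anchor matching)
  rc_reads <- reads
  rc_reads$payload <- revcomp_chr(reads$payload)
  rc_counts <- count_locus(rc_reads, tg)
  expect_identical(rc_counts[c("n_anchor_matched", "n_del", "n_ret_T",
                               "n_ret_nonT", "n_other_gap")],
                   counts[c("n_anchor_matched", "n_del", "n_ret_T",
                            "n_ret_nonT", "n_other_gap")])

  # all reads failing anchors -> zero matched
  none <- count_locus(extract_umi(reads_from_payloads(rep("ACGTACGT", 3))),
                      tg)
  expect_identical(none$n_anchor_matched, 0L)
})

test_that("single-anchor mode counts one-anchor reads only in the denominator", {
  tg <- test_target()
  payloads <- c(paste0(tg$anchor_up, "TG", tg$anchor_down),   # both anchors
                paste0(tg$anchor_up, "TGACGTACGTACGT"),        # up only
                "ACGTACGTACGTACGT")                            # neither
  reads <- extract_umi(reads_from_payloads(payloads))
  strict <- count_locus(reads, tg)
  expect_identical(strict$n_anchor_matched, 1L)
  permissive <- count_locus(reads, tg, single_anchor = TRUE)
  expect_identical(permissive$n_anchor_matched, 2L)
  expect_identical(permissive$n_del, 1L)
  expect_identical(permissive$n_other_gap, 1L)
})

test_that("signature rates follow the stated fractions and fail on no data", {
  tg <- test_target()
  payloads <- c(rep(paste0(tg$anchor_up, "TG", tg$anchor_down), 4),
                rep(paste0(tg$anchor_up, "TTG", tg$anchor_down), 5),
                paste0(tg$anchor_up, "TGG", tg$anchor_down))
  counts <- count_locus(extract_umi(reads_from_payloads(payloads)), tg)
  rates <- signature_rates(counts)
  expect_equal(rates$deletion_rate, 0.4)
  expect_equal(rates$mutation_rate, 0.1)

  pure <- count_locus(extract_umi(reads_from_payloads(
    rep(paste0(tg$anchor_up, "TTG", tg$anchor_down), 10))), tg)
  expect_equal(signature_rates(pure),
               list(deletion_rate = 0, mutation_rate = 0))

  empty <- count_locus(extract_umi(reads_from_payloads("ACGTACGTACGT")), tg)
  expect_error(signature_rates(empty), "demo_locus")
})

test_that("effective_psi normalizes, warns and clamps as specified", {
  expect_equal(effective_psi(0.35, 0.70)$effective_psi, 0.5)
  expect_equal(effective_psi(0.42, 0.42)$effective_psi, 1.0)
  expect_warning(res <- effective_psi(0.9, 0.8), "exceeds 1")
  expect_equal(res$effective_psi, 1.125)
  expect_false(res$clamped)
  clamped <- effective_psi(0.9, 0.8, clamp = TRUE)
  expect_equal(clamped$effective_psi, 1)
  expect_true(clamped$clamped)
  expect_error(effective_psi(0.5, 0), "standard")
})

test_that("quantify_locus recovers stoichiometry end to end", {
  tg <- test_target()
  sim <- simulate_cmc_reads(tg, quick_params(0.5, seed = 101, n = 10000))
  std <- simulate_standard(tg, quick_params(1, seed = 102, n = 10000),
                           kind = "psi100")
  res <- quantify_locus(sim$reads, std$reads, tg)
  expect_lt(abs(res$effective_psi - 0.5), 0.02)
  expect_identical(res$n_del + res$n_ret_T + res$n_ret_nonT +
                     res$n_other_gap, res$n_anchor_matched)

  # sample == standard file -> effective_psi exactly 1
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(std$reads, fq)
  same <- quantify_locus(fq, fq, tg)
  expect_identical(same$effective_psi, 1)

  # theta = 0 with zero backgrounds -> effective_psi 0
  zero <- simulate_cmc_reads(tg, quick_params(0, seed = 103, n = 2000))
  expect_identical(quantify_locus(zero$reads, std$reads, tg)$effective_psi, 0)
})

test_that("bias closed form holds with nonzero background deletions", {
  tg <- test_target()
  theta <- 0.5; p_del_u <- 0.02; p_del_psi <- 0.8
  effs <- vapply(1:8, function(s) {
    sim <- simulate_cmc_reads(tg, quick_params(theta, seed = 200 + s,
                                               n = 4000,
                                               p_del_psi = p_del_psi,
                                               p_del_u = p_del_u))
    std <- simulate_standard(tg, quick_params(1, seed = 300 + s, n = 4000,
                                              p_del_psi = p_del_psi,
                                              p_del_u = p_del_u),
                             kind = "psi100")
    quantify_locus(sim$reads, std$reads, tg)$effective_psi
  }, numeric(1))
  expected <- theta + (1 - theta) * p_del_u / p_del_psi
  expect_lt(abs(mean(effs) - expected), 3 * sd(effs) / sqrt(length(effs)))
})
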