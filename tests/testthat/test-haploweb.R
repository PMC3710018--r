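htab <- function(...) {
  rows <- list(...)
  haplotype_table(do.call(rbind, lapply(rows, function(r)
    data.frame(specimen = r[1], locus = r[2], allele_a = r[3],
               allele_b = r[4], stringsAsFactors = FALSE))))
}

test_that("single-locus FFRs are the closure of allele co-occurrence", {
  # s1 = (h1,h2), s2 = (h2,h2), s3 = (h3,h3): components {h1,h2} and {h3}
  h <- htab(c("s1", "L1", "h1", "h2"), c("s2", "L1", "h2", "h2"),
            c("s3", "L1", "h3", "h3"))
  f <- single_locus_ffr(h, "L1")
  expect_equal(f$n_components, 2)
  expect_equal(unname(f$membership["s1"]), unname(f$membership["s2"]))
  expect_false(f$membership[["s3"]] == f$membership[["s1"]])
  # chain s1=(h1,h2), s2=(h2,h3), s3=(h3,h4): one transitive component
  ch <- htab(c("s1", "L1", "h1", "h2"), c("s2", "L1", "h2", "h3"),
             c("s3", "L1", "h3", "h4"))
  expect_equal(single_locus_ffr(ch, "L1")$n_components, 1)
  # private homozygotes: all singleton FFRs
  pv <- htab(c("s1", "L1", "a", "a"), c("s2", "L1", "b", "b"),
             c("s3", "L1", "c", "c"))
  expect_equal(single_locus_ffr(pv, "L1")$n_components, 3)
  expect_error(single_locus_ffr(h, "L9"), "unknown locus")
})

test_that("FFRs are invariant to allele order and record order", {
  h1 <- htab(c("s1", "L1", "h1", "h2"), c("s2", "L1", "h2", "h3"))
  h2 <- htab(c("s2", "L1", "h3", "h2"), c("s1", "L1", "h2", "h1"))
  f1 <- single_locus_ffr(h1, "L1"); f2 <- single_locus_ffr(h2, "L1")
  expect_equal(f1$n_components, f2$n_components)
  expect_equal(outer(f1$membership[c("s1", "s2")],
                     f1$membership[c("s1", "s2")], "=="),
               outer(f2$membership[c("s1", "s2")],
                     f2$membership[c("s1", "s2")], "=="))
})

test_that("a bridging heterozygote merges two FFRs", {
  h <- htab(c("s1", "L1", "a", "a"), c("s2", "L1", "b", "b"))
  expect_equal(single_locus_ffr(h, "L1")$n_components, 2)
  h2 <- htab(c("s1", "L1", "a", "a"), c("s2", "L1", "b", "b"),
             c("s3", "L1", "a", "b"))
  expect_equal(single_locus_ffr(h2, "L1")$n_components, 1)
})

# 4 loci: three split {s1,s2} from {s3,s4}, one lumps everyone
three_of_four <- function() {
  rows <- list()
  for (l in c("L1", "L2", "L3")) {
    rows <- c(rows, list(c("s1", l, paste0(l, "a"), paste0(l, "a")),
                         c("s2", l, paste0(l, "a"), paste0(l, "a")),
                         c("s3", l, paste0(l, "b"), paste0(l, "b")),
                         c("s4", l, paste0(l, "b"), paste0(l, "b"))))
  }
  for (s in paste0("s", 1:4)) rows <- c(rows, list(c(s, "L4", "g", "g")))
  do.call(htab, rows)
}

test_that("the 3-of-4 majority rule splits; T = 4 lumps", {
  h <- three_of_four()
  res3 <- majority_consensus(h, min_separating = 3)
  expect_identical(canon(res3$partition), c("s1,s2", "s3,s4"))
  res4 <- majority_consensus(h, min_separating = 4)
  expect_equal(n_species(res4$partition), 1)
  # default threshold for 4 loci is a strict majority = 3
  expect_equal(majority_consensus(h)$threshold, 3L)
  expect_identical(canon(majority_consensus(h)$partition),
                   canon(res3$partition))
  # separating-locus counts are auditable
  expect_equal(res3$separating["s1", "s3"], 3L)
  expect_equal(res3$separating["s1", "s2"], 0L)
  expect_equal(res3$informative["s1", "s3"], 4L)
})

test_that("perfectly concordant loci recover the split for any T <= L", {
  rows <- list()
  for (l in paste0("L", 1:3)) {
    rows <- c(rows, list(c("s1", l, paste0(l, "x"), paste0(l, "x")),
                         c("s2", l, paste0(l, "x"), paste0(l, "x")),
                         c("s3", l, paste0(l, "y"), paste0(l, "y"))))
  }
  h <- do.call(htab, rows)
  for (T in 1:3)
    expect_identical(canon(majority_consensus(h, T)$partition),
                     c("s1,s2", "s3"))
})

test_that("consensus is monotone in the threshold", {
  set.seed(21)
  truth <- species_partition(
    stats::setNames(rep(paste0("sp", 1:3), each = 3), paste0("i", 1:9)), "t")
  h <- generate_haplotype_table(truth, n_loci = 5, admixture_rate = 0.4,
                                seed = 31)
  p1 <- majority_consensus(h, 1)$partition
  pL <- majority_consensus(h, 5)$partition
  # T = 1 refines (or equals) T = L: the meet with the coarser one is itself
  expect_identical(canon(meet(p1, pL)), canon(p1))
})

test_that("T above the locus count warns and lumps co-sampled specimens", {
  h <- three_of_four()
  expect_warning(res <- majority_consensus(h, min_separating = 5),
                 "exceeds the number of loci")
  expect_equal(n_species(res$partition), 1)
  expect_error(majority_consensus(list()), "at least")
})

test_that("malformed haplotype tables are refused; NA rows mean missing", {
  expect_error(htab(c("s1", "L1", "h1", "h1"), c("s1", "L1", "h2", "h2")),
               "more than one record")
  f <- write_tmp(c("specimen\tlocus\tallele_a\tallele_b",
                   "s1\tL1\th1\th2", "s2\tL1\tNA\tNA", "s2\tL2\th9\th9"))
  h <- read_haplotype_table(f)
  expect_equal(nrow(h), 2)   # the NA,NA record drops out as missing
  ffr <- single_locus_ffr(h, "L1")
  expect_false("s2" %in% names(ffr$membership))
})

test_that("phased FASTA input assigns equal ids to identical sequences", {
  f <- write_tmp(c(">s1", "ACGT", ">s1", "acgt",
                   ">s2", "ACGT", ">s2", "AGGT"), ".fasta")
  h <- read_phased_fasta(f, "cmos")
  expect_s3_class(h, "haplotype_table")
  # s1 is homozygous (case-insensitive match); s2 shares one allele with s1
  r1 <- h[h$specimen == "s1", ]
  expect_identical(r1$allele_a, r1$allele_b)
  f2 <- single_locus_ffr(h, "cmos")
  expect_equal(f2$n_components, 1)
  bad <- write_tmp(c(">s1", "ACGT"), ".fasta")
  expect_error(read_phased_fasta(bad, "x"), "two sequences")
})
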