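test_that("read_fasta parses minimal, wrapped and multi-record files", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), p)
  g <- read_fasta(p)
  expect_equal(names(g), "chr1")
  expect_equal(as.character(g[["chr1"]]), "ACGT")

  # 3 records with 60-column wrapping; compare against an independent
  # line-by-line parse
  set.seed(11)
  seqs <- vapply(c(150L, 61L, 200L), random_dna, character(1))
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    chunks <- substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s)))
    c(paste0(">ctg", i, " description text"), chunks)
  }))
  writeLines(lines, p)
  g <- read_fasta(p)
  expect_equal(names(g), c("ctg1", "ctg2", "ctg3"))
  expect_equal(unname(as.character(g)), unname(seqs))

  # lower-case input is uppercased
  writeLines(c(">x", "acgtn"), p)
  expect_equal(as.character(read_fasta(p)[["x"]]), "ACGTN")

  # duplicate names error
  writeLines(c(">a", "ACGT", ">a", "GGCC"), p)
  expect_error(read_fasta(p), "duplicate")
})

test_that("FASTA write/read round-trips any valid genome", {
  set.seed(5)
  genome <- Biostrings::DNAStringSet(
    setNames(c(random_dna(101), random_dna(60), random_dna(59)),
             c("c1", "c2", "c3"))
  )
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(genome, p)
  back <- read_fasta(p)
  expect_equal(as.character(back), as.character(genome))
})

test_that("read_vcf computes VAF, drops hom-ref rows via variant_calls and splits multiallelics", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t60\t.\t.\tGT:DP:AD\t1:20:0,20\t0:18:18,0",
    "chr1\t200\t.\tG\tC\t55\t.\t.\tGT:DP:AD\t0:10:10,0\t0:12:12,0",
    "chr1\t300\t.\tC\tA,G\t50\t.\t.\tGT:DP:AD\t1:30:0,27,3\t2:30:1,0,29"
  ), p)
  tbl <- read_vcf(p)
  calls <- variant_calls(tbl)
  # fixed haploid variant: vaf 1.0
  c1 <- calls[calls$pos == 100, ]
  expect_equal(c1$sample_id, "s1")
  expect_equal(c1$vaf, 1.0)
  # all-hom-ref record emits no call
  expect_false(200 %in% calls$pos)
  # but its depths remain available in the long table
  expect_equal(sort(tbl$depth[tbl$pos == 200]), c(10L, 12L))
  # multiallelic split: two biallelic sites with the right carriers
  c3 <- calls[calls$pos == 300, ]
  expect_equal(nrow(c3), 2L)
  expect_equal(c3$alt[c3$sample_id == "s1"], "A")
  expect_equal(c3$alt_depth[c3$sample_id == "s1"], 27L)
  expect_equal(c3$alt[c3$sample_id == "s2"], "G")
  expect_equal(c3$vaf[c3$sample_id == "s2"], 29 / 30)
})

test_that("records without DP/AD are skipped with a warning; bad header errors", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t60\t.\t.\tGT\t1",
    "chr1\t150\t.\tG\tC\t60\t.\t.\tGT:DP:AD\t1:9:1,8"
  ), p)
  expect_warning(tbl <- read_vcf(p), "skipped")
  expect_equal(tbl$pos, 150L)

  writeLines(c("##fileformat=VCFv4.2", "chr1\t1\t.\tA\tT\t1\t.\t."), p)
  expect_error(read_vcf(p), "header")
})

test_that("indels are parsimony-trimmed and left-aligned against a genome", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGTTTTACGTACGT"))
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    # shared-suffix representation: TTTTA > TA trims to TTTT > T at pos 3
    "chr1\t3\t.\tTTTTA\tTA\t60\t.\t.\tGT:DP:AD\t1:20:2,18",
    # right-aligned single-T deletion at pos 5 shifts left through the
    # homopolymer to pos 3
    "chr1\t5\t.\tTT\tT\t60\t.\t.\tGT:DP:AD\t1:20:2,18"
  ), p)
  tbl <- read_vcf(p, genome = genome)
  expect_equal(tbl$pos, c(3L, 3L))
  expect_equal(sort(tbl$ref), c("TT", "TTTT"))
  expect_equal(tbl$alt, c("T", "T"))
  expect_equal(unique(tbl$var_type), "InDel")
})

test_that("simulator-written VCF round-trips to the identical call set", {
  cfg <- simulation_config(seed = 3L, n_ref_polymorphisms = 20L,
                           n_lineage_polymorphisms = 5L)
  sim <- simulate_experiment(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  back <- read_vcf(file.path(d, "variants.vcf"))
  ord <- function(x) dplyr::arrange(x, chrom, pos, ref, alt, sample_id)
  a <- ord(sim$vcf)
  b <- ord(back)
  for (col in c("chrom", "pos", "ref", "alt", "var_type", "size_class",
                "sample_id", "gt", "depth", "alt_depth")) {
    expect_equal(a[[col]], b[[col]], info = col)
  }
  expect_equal(a$vaf, b$vaf, tolerance = 1e-9)
  expect_equal(a$qual, b$qual, tolerance = 1e-4)
})

test_that("write_bed converts coordinates and round-trips; bad intervals error", {
  sites <- tibble::tibble(chrom = "chr1", start = 100L, end = 123L,
                          strand = "+", mismatches = 3L,
                          nuclease_id = "sgRNA1")
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(sites, p)
  # 1-based inclusive span 101-123 == BED 100/123
  expect_equal(readLines(p), "chr1\t100\t123\tsgRNA1\t3\t+")
  back <- read_bed(p)
  expect_equal(back$start, sites$start)
  expect_equal(back$end, sites$end)
  expect_equal(back$strand, sites$strand)

  # empty site list -> empty file
  write_bed(sites[0, ], p)
  expect_length(readLines(p), 0L)

  expect_error(write_bed(dplyr::mutate(sites, end = 100L), p), "end > start")
})

test_that("metadata validation enforces the lineage invariants", {
  md <- study_design_metadata()
  expect_equal(nrow(md), 15L)
  expect_equal(sum(!md$excluded), 14L)
  expect_equal(dplyr::n_distinct(md$experiment_group), 3L)
  # round-trip through TSV
  p <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, p)
  expect_equal(as.data.frame(read_metadata(p)), as.data.frame(md))

  # one WT alone is a valid single-group design
  solo <- tibble::tibble(sample_id = "WT", experiment_group = "A",
                         lineage_wt = "WT", role = "wildtype")
  expect_silent(validate_metadata(solo))

  # two wildtypes in one group
  dup <- dplyr::bind_rows(solo, dplyr::mutate(solo, sample_id = "WT2",
                                              lineage_wt = "WT2"))
  expect_error(validate_metadata(dup), "exactly one wildtype")

  # dangling lineage reference
  dangling <- dplyr::bind_rows(
    solo, tibble::tibble(sample_id = "P", experiment_group = "A",
                         lineage_wt = "nope", role = "peg")
  )
  expect_error(validate_metadata(dangling), "dangling")

  # edited sample must name its nuclease
  ed <- dplyr::bind_rows(
    solo, tibble::tibble(sample_id = "E", experiment_group = "A",
                         lineage_wt = "WT", role = "edited")
  )
  expect_error(validate_metadata(ed), "nuclease_id")
})
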