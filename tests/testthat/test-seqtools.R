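test_that("blast tabular lines map field-for-field onto hit records", {
  hit <- parse_blast_tabular(
    "q\ts\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-50\t200")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$query_id, "q")
  expect_equal(hit$pct_identity, 98.5)
  expect_equal(hit$e_value, 1e-50)
  expect_equal(hit$bit_score, 200)

  with_comments <- c("# BLASTP 2.16", "# Query: q",
                     "q\ts1\t90\t80\t8\t0\t1\t80\t1\t80\t1e-20\t150",
                     "q\ts2\t80\t70\t14\t1\t5\t74\t1\t70\t1e-10\t100")
  hits <- parse_blast_tabular(with_comments)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$subject_id, c("s1", "s2"))
})

test_that("a 10-line fixture equals an independent tab tokenizer", {
  set.seed(3)
  lines <- vapply(1:10, function(i) {
    paste(c(paste0("q", i), paste0("s", i),
            sprintf("%.2f", runif(1, 20, 100)), i * 10, i, i %% 3,
            1, i * 10, 5, 5 + i * 10 - 1,
            sprintf("%.1e", 10^-runif(1, 1, 60)),
            sprintf("%.1f", runif(1, 50, 500))), collapse = "\t")
  }, character(1))
  hits <- parse_blast_tabular(lines)
  ref <- strsplit(lines, "\t", fixed = TRUE)
  for (i in 1:10) {
    expect_equal(hits$query_id[i], ref[[i]][1])
    expect_equal(hits$pct_identity[i], as.numeric(ref[[i]][3]))
    expect_equal(hits$aln_length[i], as.integer(ref[[i]][4]))
    expect_equal(hits$q_end[i], as.integer(ref[[i]][8]))
    expect_equal(hits$e_value[i], as.numeric(ref[[i]][11]))
  }
})

test_that("malformed blast rows are rejected with their line number", {
  expect_error(parse_blast_tabular("q\ts\t90\t100"), "line 1")
  expect_error(
    parse_blast_tabular(c("# ok",
                          "q\ts\tNOTNUM\t100\t1\t0\t1\t100\t1\t100\t1e-5\t50")),
    "line 2")
})

test_that("the Rost curve has the canonical shape", {
  # closed-form spot value, recomputed independently of the function
  L <- 250
  expect_equal(rost_threshold(250, 5),
               5 + 480 * L^(-0.32 * (1 + exp(-L / 1000))))
  # strictly decreasing over the alignment lengths where the curve is used
  # as a homology threshold (the closed form has its minimum near L ~ 417,
  # beyond which it slowly rises and has no biological use)
  v <- rost_threshold(10:400, 5)
  expect_true(all(diff(v) < 0))
  # long-alignment behaviour: well below the short-alignment regime and
  # approaching the L^-0.32 tail of the closed form
  expect_lt(rost_threshold(100000, 0), 480 * 100000^-0.32 + 1e-9)
  expect_lt(rost_threshold(100000, 5), rost_threshold(50, 5))
  # offset linearity, exact
  expect_equal(rost_threshold(137, 20) - rost_threshold(137, 3), 17)
  expect_error(rost_threshold(0), ">= 1")
})

test_that("filter_hits equals brute-force per-hit evaluation and is idempotent", {
  set.seed(42)
  n <- 20
  hits <- tibble::tibble(
    query_id = "q", subject_id = paste0("s", 1:n),
    pct_identity = seq(10, 95, length.out = n),
    aln_length = sample(30:400, n, replace = TRUE),
    mismatches = 0L, gap_opens = 0L,
    q_start = sample(1:50, n, replace = TRUE),
    q_end = 0L, s_start = 1L, s_end = 0L,
    e_value = 10^-runif(n, 0, 40), bit_score = runif(n, 40, 400))
  hits$q_end <- hits$q_start + sample(40:250, n, replace = TRUE)
  qlen <- 300

  f <- hit_filter(max_evalue = 1e-5, min_coverage = 0.5, min_identity = 25,
                  use_rost = TRUE, rost_n = 5)
  got <- filter_hits(hits, qlen, f)
  keep <- vapply(1:n, function(i) {
    h <- hits[i, ]
    h$e_value <= 1e-5 &&
      (h$q_end - h$q_start + 1) / qlen >= 0.5 &&
      h$pct_identity >= 25 &&
      h$pct_identity >= 5 + 480 * h$aln_length^
        (-0.32 * (1 + exp(-h$aln_length / 1000)))
  }, logical(1))
  expect_equal(got$subject_id, hits$subject_id[keep])
  expect_identical(filter_hits(got, qlen, f), got)

  # permissive filter is the identity
  expect_identical(filter_hits(hits, qlen, hit_filter()), hits)
  # a single criterion failing removes the hit
  low_cov <- hits[1, ]
  low_cov$e_value <- 0; low_cov$pct_identity <- 99
  low_cov$q_start <- 1L; low_cov$q_end <- 10L
  expect_equal(nrow(filter_hits(low_cov, qlen,
                                hit_filter(min_coverage = 0.5))), 0)
})

test_that("PIR output is minimal and exact for a 1-residue alignment", {
  p <- write_pir("q", "A", "t", "A", template_chain = "X",
                 template_start = 7, template_end = 7)
  expect_equal(p, c(">P1;t", "structureX:t:7:X:7:X::::", "A*",
                    ">P1;q", "sequence:q::::::::", "A*"))
})

test_that("sequences wrap at 60 columns with a single terminator", {
  p <- write_pir("q", strrep("A", 150), "t", strrep("G", 150))
  bodies <- split(p[c(3:5, 8:10)], rep(1:2, each = 3))
  for (b in bodies) expect_equal(nchar(b), c(60, 60, 31))
  # length an exact multiple of 60: terminator on its own line
  p2 <- write_pir("q", strrep("A", 120), "t", strrep("G", 120))
  expect_equal(p2[5], "*")
  expect_error(write_pir("q", "AC", "t", "A"), "length")
  expect_error(write_pir("q", "A*", "t", "AA"), "terminator")
  expect_error(write_pir("q", "", "t", ""), "empty")
})

test_that("random alignments round-trip through the PIR grammar oracle", {
  set.seed(9)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  for (rep in 1:50) {
    len <- sample(1:200, 1)
    qs <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
    ts <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
    lines <- write_pir("query1", qs, "tmpl1", ts, template_chain = "B",
                       template_start = 3, template_end = 3 + len - 1)
    entries <- read_pir_oracle(lines)
    expect_length(entries, 2)
    expect_equal(sum(lines == "*" | grepl("\\*$", lines)), 2)
    expect_equal(length(grep("^>P1;", lines)), 2)
    expect_equal(entries[[1]]$id, "tmpl1")
    expect_equal(entries[[1]]$desc[1], "structureX")
    expect_equal(entries[[1]]$desc[3], "3")
    expect_equal(entries[[1]]$desc[4], "B")
    expect_equal(entries[[1]]$seq, ts)
    expect_equal(entries[[2]]$id, "query1")
    expect_equal(entries[[2]]$desc[1], "sequence")
    expect_equal(entries[[2]]$seq, qs)
  }
})
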