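test_that("flanking markers resolve to normalised physical intervals", {
  mq <- data.frame(name = c("MQTL1.1", "MQTL1.2", "MQTL1.3", "MQTL1.4"),
                   chr = 1L,
                   flank_left = c("A", "missing", "B", "A"),
                   flank_right = c("B", "B", "A", "C"),
                   stringsAsFactors = FALSE)
  lookup <- data.frame(marker = c("A", "B", "C"),
                       chr = c(1L, 1L, 2L),
                       pos_bp = c(1200000, 3400000, 500000),
                       stringsAsFactors = FALSE)
  res <- resolve_physical(mq, lookup)
  expect_equal(res$intervals$start_bp[1], 1200000)
  expect_equal(res$intervals$end_bp[1], 3400000)
  # reversed flank order still yields [min, max]
  expect_equal(res$intervals$start_bp[2], 1200000)
  expect_equal(res$intervals$mqtl_name[2], "MQTL1.3")
  expect_equal(res$unresolved$reason,
               c("NO_MARKER_POSITION", "MARKER_CHR_CONFLICT"))
})

test_that("gene extraction honours the 1 bp overlap rule on a toy GFF3", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(gff)
  iv <- data.frame(chr = 1L, start_bp = 1000000, end_bp = 2000000)
  genes <- extract_genes(iv, gff)
  # g2 straddles the interval start, g3 inside, g4 straddles the end
  expect_equal(genes$gene_id, c("g2", "g3", "g4"))
  expect_equal(genes$strand, c("-", "+", "+"))
  expect_equal(genes$description, c("beta", "gamma", "delta"))
  # empty region
  empty <- extract_genes(data.frame(chr = 1L, start_bp = 3e6,
                                    end_bp = 4e6), gff)
  expect_equal(nrow(empty), 0)
  # other chromosome not picked up
  chr2 <- extract_genes(data.frame(chr = 2L, start_bp = 1, end_bp = 1e7), gff)
  expect_equal(chr2$gene_id, "g6")
})

test_that("gene extraction is invariant to feature order", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  lines <- readLines(write_toy_gff3(gff))
  shuffled <- c(lines[1], lines[c(5, 2, 7, 3, 6, 4)])
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(shuffled, gff2)
  iv <- data.frame(chr = 1L, start_bp = 1000000, end_bp = 2000000)
  expect_equal(extract_genes(iv, gff), extract_genes(iv, gff2))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # the worked case: N=20 background, K=5 with the term, n=5 drawn, k=3
  background <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = background[1:5], term_id = "GO:1")
  gene_set <- c(background[1:3], background[19:20])
  res <- go_enrichment(gene_set, ann, background)
  expect_equal(res$p_value, 0.07262, tolerance = 1e-4)
  expect_equal(res$p_value, oracle_hyper_upper(3, 5, 20, 5),
               tolerance = 1e-12)
  expect_equal(res$fdr, res$p_value)  # single term: BH is identity
  # k = 0 is the certain event
  res0 <- go_enrichment(background[6:10], ann, background)
  expect_equal(res0$p_value, 1.0)
  expect_error(go_enrichment("ghost", ann, background), "absent")
})

test_that("enrichment p-values match the enumeration oracle across many designs", {
  set.seed(17)
  for (rep in 1:20) {
    N <- sample(8:25, 1)
    background <- sprintf("b%02d", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ann <- data.frame(gene_id = sample(background, K), term_id = "T")
    gene_set <- sample(background, n)
    res <- go_enrichment(gene_set, ann, background)
    k <- sum(gene_set %in% ann$gene_id)
    expect_equal(res$p_value, oracle_hyper_upper(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("BH-adjusted FDRs are monotone in p-value rank", {
  background <- sprintf("g%02d", 1:30)
  set.seed(23)
  ann <- do.call(rbind, lapply(1:8, function(t)
    data.frame(gene_id = sample(background, sample(3:12, 1)),
               term_id = paste0("GO:", t))))
  res <- go_enrichment(sample(background, 10), ann, background)
  expect_false(is.unsorted(res$fdr))      # sorted by p: fdr non-decreasing
  expect_true(all(res$fdr <= 1))
})

test_that("expression ranking scores fold change with a pseudocount guard", {
  expr <- rbind(hot = c(10, 10, 1, 1), flat = c(3, 3, 3, 3),
                zero = c(0, 0, 0, 0))
  colnames(expr) <- c("anther", "pistil", "shoot", "root")
  res <- expression_rank(rownames(expr), expr,
                         target_tissues = c("anther", "pistil"))
  sc <- res$scores
  expect_equal(sc$score[sc$gene_id == "hot"], 10.1 / 1.1, tolerance = 1e-12)
  expect_equal(sc$score[sc$gene_id == "flat"], 1.0)
  expect_equal(sc$score[sc$gene_id == "zero"], 1.0)
  expect_equal(res$shortlist$gene_id, "hot")
  # shortlist shrinks as the threshold rises
  res5 <- expression_rank(rownames(expr), expr,
                          target_tissues = c("anther", "pistil"),
                          fold_threshold = 20)
  expect_true(all(res5$shortlist$gene_id %in% res$shortlist$gene_id))
  # absent genes are flagged, not dropped silently
  res_m <- expression_rank(c("hot", "ghost"), expr,
                           target_tissues = c("anther", "pistil"))
  expect_equal(res_m$missing, "ghost")
  expect_error(expression_rank("hot", expr, target_tissues = "petal"),
               "no target tissue")
})

test_that("BED export converts 1-based inclusive to 0-based half-open", {
  iv <- data.frame(mqtl_name = "M", chr = 3L, start_bp = 101, end_bp = 200)
  path <- withr::local_tempfile(fileext = ".bed")
  write_intervals_bed(iv, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 200)
  expect_equal(bed$V1, "Chr3")
})
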