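# shared fixtures: a 5 x 10 Mb test genome and compact library plans
test_genome <- function() genome_spec(paste0("chr", 1:5), rep(1e7, 5))

# mate-pair-like plan with a tight SD so every SV class is classifiable
tight_plan <- function(n_pairs = 2e5, seed = 1, purity = 1)
  library_plan(3000, 150, 50, n_pairs, purity, seed)

# wide mate-pair plan emulating the real libraries (mean 2554, SD 719)
wide_plan <- function(n_pairs = 1e5, seed = 1, purity = 1)
  library_plan(2554, 719, 50, n_pairs, purity, seed)

# one synthetic SV call table row
make_call <- function(chrom1, start1, end1, chrom2, start2, end2,
                      sv_type = "deletion", strand1 = "+", strand2 = "-",
                      support = 3, sample_id = "T", call_id = "c1") {
  data.frame(sample_id = sample_id, sv_type = sv_type,
             chrom1 = chrom1, start1 = start1, end1 = end1,
             strand1 = strand1,
             chrom2 = chrom2, start2 = start2, end2 = end2,
             strand2 = strand2, support = support, call_id = call_id,
             stringsAsFactors = FALSE)
}

# brute-force single-linkage components: all-pairs adjacency + BFS
brute_components <- function(pos1, pos2, d_max) {
  n <- length(pos1)
  adj <- outer(pos1, pos1, function(a, b) abs(a - b) <= d_max) &
    outer(pos2, pos2, function(a, b) abs(a - b) <= d_max)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
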