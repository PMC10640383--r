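# small synthetic worlds reused across tests (kept far below the
# full-scale defaults so the module suite stays fast)

small_truth <- function(seed = 1, depth = NULL, host_len = 3e5,
                        insert_len = 1e5, host_orfs = 150,
                        decay = decay_model()) {
  reads <- if (is.null(depth)) {
    NULL
  } else {
    read_sim_model(depth = depth, read_length_mean = 6000,
                   read_length_sd = 1500, error_rate = 0.02,
                   seed = seed + 100)
  }
  simulate_endogenization(
    host = host_model(length = host_len, repeat_fraction = 0.3),
    insert = insert_model(length = insert_len),
    decay = decay,
    reads = reads, host_orfs = host_orfs, seed = seed)
}

# truth-side junction oracle: reads whose true sampled interval crosses a
# boundary with >= min_anchor bases strictly on each side
oracle_junction_ids <- function(paf, region, min_anchor) {
  t1 <- paf$tstart + 1
  t2 <- paf$tend
  rs <- region$start
  re <- region$end
  left <- t1 <= rs - min_anchor & pmin(t2, re) >= rs + min_anchor - 1
  right <- t2 >= re + min_anchor & pmax(t1, rs) <= re - min_anchor + 1
  sort(unique(paf$qname[left | right]))
}
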