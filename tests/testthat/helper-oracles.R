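# analytic oracle for the expected number of detectable junction-spanning
# long reads: integrates the gamma length distribution by Monte Carlo
# (independent of the simulator's own sampling path)
spanning_expectation <- function(hap_len, insert_iv, depth, mean_len,
                                 min_len = 300L, f_near = 1L, f_far = 1L,
                                 n_mc = 2e5) {
  n_reads <- round(hap_len * depth / 2 / mean_len)
  L <- pmin(hap_len, pmax(min_len, round(rgamma(n_mc, shape = 3,
                                                scale = mean_len / 3))))
  b1 <- insert_iv[1]; b2 <- insert_iv[2]
  # start ranges (0-based, inclusive) from which a read of length L covers
  # junction 1 or junction 2 with the required flanks
  union_len <- function(L) {
    lo1 <- pmax(b1 - L + f_far, 0); hi1 <- b1 - f_near   # Y|X junction
    lo2 <- pmax(b2 - L + f_near, 0); hi2 <- b2 - f_far   # X|Y junction
    len1 <- pmax(0, hi1 - lo1 + 1); len2 <- pmax(0, hi2 - lo2 + 1)
    ov <- pmax(0, pmin(hi1, hi2) - pmax(lo1, lo2) + 1)
    len1 + len2 - ov
  }
  p <- union_len(L) / (hap_len - L + 1)
  n_reads * mean(p)
}

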