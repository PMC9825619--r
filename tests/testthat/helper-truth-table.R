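# exhaustive 12-case truth table: each rule violated in isolation at and
# beyond its boundary, plus the all-pass case
filter_truth_table <- function() {
  pro <- filter_thresholds("prokaryote")
  euk <- filter_thresholds("eukaryote")
  scatter <- function(n_lcr) lapply(seq_len(n_lcr) * 3 - 2,
                                    function(s) c(s, 1, 50))
  list(
    # profile, thresholds, passed, browse
    list(make_plddt_profile(200, background = 95), pro, TRUE, TRUE),
    list(make_plddt_profile(200, scatter(20)), pro, FALSE, FALSE),   # 10% exact
    list(make_plddt_profile(200, scatter(30)), pro, FALSE, FALSE),   # 15% beyond
    list(make_plddt_profile(200, scatter(39)), euk, TRUE, TRUE),     # 19.5% euk ok
    list(make_plddt_profile(200, scatter(40)), euk, FALSE, FALSE),   # 20% exact
    list(make_plddt_profile(200, list(c(100, 15, 50))), pro, FALSE, FALSE), # run 15
    list(make_plddt_profile(200, list(c(100, 14, 50))), pro, TRUE, TRUE),   # run 14
    list(make_plddt_profile(200, list(c(100, 25, 50))), euk, FALSE, FALSE), # run 25
    list(make_plddt_profile(200, list(c(100, 24, 50))), euk, TRUE, TRUE),   # run 24
    list(make_plddt_profile(200, list(c(1, 20, 69.9))), euk, FALSE, FALSE), # n-term
    list(make_plddt_profile(50, background = 95), pro, FALSE, FALSE),       # size 50
    list(make_plddt_profile(100, background = 95), pro, TRUE, FALSE)        # browse gate
  )
}
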