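# Shared fixtures built in code.

# the reference parameter set used throughout the unit tests (root 64 = E4,
# admitted explicitly since it is outside the default root set)
test_params <- function(x0 = 64, l = 4, t = 4, c = +1) {
  rule_params(x0, l, t, c, root_set = c(default_root_set(), 64L))
}

# every stimulus in the default pool as a list of rule_params
pool_params <- function() {
  pool <- enumerate_pool()
  lapply(seq_len(nrow(pool)), function(i)
    rule_params(pool$x0[i], pool$l[i], pool$t[i], pool$c[i]))
}

# pitch sequence of the terminal tones in temporal order
leaf_pitches <- function(step) {
  ev <- schedule_events(step, mode = "leaves")
  ev$pitch[order(ev$onset)]
}
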