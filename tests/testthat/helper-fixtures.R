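# shared fixtures: confidence-stratified call frames and the published
# operating points used in table-driven tests

make_calls <- function(labels, confs) {
  data.frame(label = as_depth_label(labels),
             confidence = factor(confs, levels = c("low", "high"),
                                 ordered = TRUE))
}

# printed (sensitivity, specificity) pairs with their class sizes:
# individual raters and panel subsets on the 250/250 internal cohort,
# fusion patterns on the same cohort, and the three sources on the
# 100/100 independent test cohort
published_operating_points <- function() {
  rbind(
    data.frame(source = c("A", "B", "C", "D", "E", "F", "G", "H"),
               sens = c(.616, .544, .432, .600, .468, .548, .520, .624),
               spec = c(.760, .892, .900, .696, .772, .756, .688, .632),
               n_pos = 250, n_neg = 250),
    data.frame(source = c("ABC", "ABD", "ACD", "BCD"),
               sens = c(.536, .572, .544, .540),
               spec = c(.916, .784, .792, .900),
               n_pos = 250, n_neg = 250),
    data.frame(source = c("patternI", "patternII", "patternIII", "patternIV"),
               sens = c(.692, .556, .744, .608),
               spec = c(.888, .948, .848, .908),
               n_pos = 250, n_neg = 250),
    data.frame(source = c("ai_test", "panel_test", "coop_test"),
               sens = c(.740, .520, .760),
               spec = c(.710, .880, .800),
               n_pos = 100, n_neg = 100)
  )
}

# hand-enumerated decision table: all sixteen (AI state, panel state)
# cells with the expected route and final label under each pattern.
# Written out literally, independently of the implementation: agreement
# keeps the shared label; differing labels at differing confidence go to
# the higher-confidence source; differing labels at equal confidence are
# mismatch 1 (AI SM / panel M) or mismatch 2 (AI M / panel SM), split by
# pattern.
fusion_truth_table <- function() {
  read.csv(text = "ai_label,ai_conf,panel_label,panel_conf,route,I,II,III,IV
M,high,M,high,agreement,M,M,M,M
M,high,M,low,agreement,M,M,M,M
M,high,SM,high,mismatch2,M,M,SM,SM
M,high,SM,low,confidence_override,M,M,M,M
M,low,M,high,agreement,M,M,M,M
M,low,M,low,agreement,M,M,M,M
M,low,SM,high,confidence_override,SM,SM,SM,SM
M,low,SM,low,mismatch2,M,M,SM,SM
SM,high,M,high,mismatch1,SM,M,SM,M
SM,high,M,low,confidence_override,SM,SM,SM,SM
SM,high,SM,high,agreement,SM,SM,SM,SM
SM,high,SM,low,agreement,SM,SM,SM,SM
SM,low,M,high,confidence_override,M,M,M,M
SM,low,M,low,mismatch1,SM,M,SM,M
SM,low,SM,high,agreement,SM,SM,SM,SM
SM,low,SM,low,agreement,SM,SM,SM,SM",
           stringsAsFactors = FALSE)
}
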