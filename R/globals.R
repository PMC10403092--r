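## data.table non-standard-evaluation column names
utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "action", "available_minutes", "day", "day_max",
  "encounter_id", "epp", "ewt_hours", "frac_ctrl", "frac_mv", "group",
  "group_rank", "hi", "hit", "i.win_id", "in_train", "label", "lo",
  "max_pews", "med_pos", "medication", "mv_flag", "mv_onset_time", "n",
  "n_ctrl_pat", "n_mv_pat", "pews", "pred", "prior", "reason", "rule_id",
  "score", "score_B", "sequence_no", "seq", "time", "tmax", "variable",
  "value", "value_cat", "win_id", "x.n", "x.sequence_no", "x.time",
  "x.value", "x.value_cat", "x.medication", "x.action", "discharge_time",
  "escalation", "..cols"))
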