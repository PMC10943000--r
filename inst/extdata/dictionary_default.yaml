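# Seed term dictionary for note mining.  The matching engine, not this
# lexicon, is the contract: extend or replace per site.  ASCII terms match
# at word boundaries, Japanese terms as substrings.
terms:
  history_of_hypertension: [history of hypertension, hypertension, chronic hypertension, high blood pressure, "高血圧"]
  epigastralgia: [epigastralgia, epigastric pain, "心窩部痛"]
  hellp_syndrome: [hellp syndrome, hellp, "ＨＥＬＬＰ"]
  eclampsia: [eclampsia, eclamptic seizure, "子癇"]
  fgr: [fgr, fetal growth restriction, iugr, "胎児発育不全"]
  renal_dysfunction: [renal dysfunction, renal insufficiency, "腎機能障害"]
  hepatic_dysfunction: [hepatic dysfunction, liver dysfunction, "肝機能障害"]
  new_onset_headache: [new-onset headache, new onset headache, severe headache, "頭痛"]
  visual_disturbance: [visual disturbance, blurred vision, scotoma, "視力障害"]
  pulmonary_edema: [pulmonary edema, pulmonary oedema, "肺水腫"]
negation_cues: [no, not, without, denies, negative for, "なし", "否定"]
post_negation_cues: [ruled out, not present, "なし"]
negation_window: 10
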