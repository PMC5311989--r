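{
  "bank_id": "mdd-dsm5-core",
  "version": "1.0",
  "entry": "a1",
  "nodes": [
    { "id": "a1", "criterion": "A1",
      "text": "Over the past two weeks, have you felt sad, down, or depressed most of the day, nearly every day?",
      "response_kind": "binary", "branch": { "yes": "a2", "no": "a2" } },
    { "id": "a2", "criterion": "A2",
      "text": "Over the past two weeks, have you lost interest or pleasure in almost all of the things you usually enjoy?",
      "response_kind": "binary", "branch": { "yes": "a3", "no": "a3" } },
    { "id": "a3", "criterion": "A3",
      "text": "Has your appetite or weight changed noticeably (either up or down) without trying, nearly every day?",
      "response_kind": "binary", "branch": { "yes": "a4", "no": "a4" } },
    { "id": "a4", "criterion": "A4",
      "text": "Have you had trouble sleeping, or been sleeping much more than usual, nearly every night?",
      "response_kind": "binary", "branch": { "yes": "a5", "no": "a5" } },
    { "id": "a5", "criterion": "A5",
      "text": "Have you been moving or speaking so slowly, or been so fidgety and restless, that other people could have noticed, nearly every day?",
      "response_kind": "binary", "branch": { "yes": "a6", "no": "a6" } },
    { "id": "a6", "criterion": "A6",
      "text": "Have you been feeling tired or lacking in energy nearly every day?",
      "response_kind": "binary", "branch": { "yes": "a7", "no": "a7" } },
    { "id": "a7", "criterion": "A7",
      "text": "Have you been feeling worthless, or excessively or inappropriately guilty, nearly every day?",
      "response_kind": "binary", "branch": { "yes": "a8", "no": "a8" } },
    { "id": "a8", "criterion": "A8",
      "text": "Have you had trouble thinking, concentrating, or making decisions, nearly every day?",
      "response_kind": "binary", "branch": { "yes": "a9", "no": "a9" } },
    { "id": "a9", "criterion": "A9",
      "text": "Have you had recurrent thoughts of death, or thoughts that you would be better off dead, or thoughts of harming yourself?",
      "response_kind": "binary", "branch": { "yes": "dur", "no": "dur" } },
    { "id": "dur", "criterion": "DUR",
      "text": "Have these difficulties been present together during the same two-week period, representing a change from how you usually are?",
      "response_kind": "binary", "branch": { "yes": "imp", "no": "imp" } },
    { "id": "imp", "criterion": "B",
      "text": "Do these difficulties cause you significant distress, or interfere with your work, social life, or other important areas of your life?",
      "response_kind": "binary", "branch": { "yes": "END", "no": "END" } }
  ]
}
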