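# Tiny OBO fixtures shared across test files.

obo_chain <- paste(
  "format-version: 1.2",
  "",
  "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
  "",
  "[Term]", "id: GO:0000002", "name: a", "namespace: biological_process",
  "is_a: GO:0000001 ! root",
  "",
  "[Term]", "id: GO:0000003", "name: b", "namespace: biological_process",
  "is_a: GO:0000002 ! a",
  "",
  "[Term]", "id: GO:0000004", "name: c", "namespace: biological_process",
  "is_a: GO:0000003 ! b",
  sep = "\n")

# diamond: term 5 reaches the root via a 2-edge and a 4-edge path
obo_diamond <- paste(
  obo_chain,
  "",
  "[Term]", "id: GO:0000005", "name: d", "namespace: biological_process",
  "is_a: GO:0000002 ! a",
  "is_a: GO:0000004 ! c",
  sep = "\n")
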