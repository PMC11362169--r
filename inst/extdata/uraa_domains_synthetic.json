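{
  "note": "RECONSTRUCTION: approximate UraA (E. coli, 429 aa) selections assembled from the published topology (scaffold = TM5-7 + TM12-14, transport = TM1-4 + TM8-11). The source study does not print its residue ranges; edit these to match your own domain definitions before quantitative use.",
  "chain": "A",
  "scaffold": "A:122-196,A:331-410",
  "transport": "A:12-110,A:222-317",
  "spacer_helix_external": "A:321-329",
  "spacer_helix_cytoplasmic": "A:113-120",
  "tm11": "A:300-317",
  "tm4": "A:95-110",
  "binding_site": "A:241-241,A:245-245,A:290-290",
  "interdomain_linker_cytoplasmic": "A:111-121",
  "interdomain_linker_external": "A:318-330"
}
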