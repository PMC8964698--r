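targets:
- name: example_CBE
  amplicon_fasta: example_amplicon.fasta
  protospacer_start: 30
  protospacer_strand: +
  editor: CBE
  intended_positions: 6
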