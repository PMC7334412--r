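# Example strategy definition: the NKp80-based CD56neg gate with CD123
# added to the exclusion channel.
name: nkp80_custom
exclusion: [Viability, CD3, CD14, CD19, CD123]
target: target
parent: CD56neg
subsets:
  CD56neg:
    marker: CD56
    polarity: negative
  target:
    and:
      - {marker: CD56, polarity: negative}
      - {marker: NKp80, polarity: positive}
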