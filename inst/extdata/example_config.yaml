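# Example region/clade configuration for a synthetic 160-column domain.
# Reference coordinates are 1-based positions on the ungapped reference row.
reference: t001
regions:
  domain: [1, 160]
  hotspot1: [30, 86]
  hotspot2: [105, 147]
phosphosites: [3, 7, 11, 26, 30, 37, 44, 54, 57, 61, 68, 77, 84, 87, 96, 108, 112, 117, 121, 126, 131, 135, 142, 148, 150, 152, 154, 156, 157, 158, 159, 160]
stickers: [6, 14, 17, 25, 33, 38, 41, 50, 55, 58, 66, 75, 81, 91, 97, 100]
clades:
  focal: [t001, t002, t003, t004, t005]
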