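# Secondary-structure elements of darcin (MUP20), mature-protein numbering.
# Strands/helices from the solution-structure inventory; loops are the
# inter-element gaps (L1 between b1 and b2, ..., L9 between a1 and b9).
elements:
  - {name: "310a", start: 12, end: 14, kind: "310"}
  - {name: "b1", start: 20, end: 26, kind: "strand"}
  - {name: "L1", start: 27, end: 40, kind: "loop"}
  - {name: "310b", start: 34, end: 36, kind: "310"}
  - {name: "b2", start: 41, end: 47, kind: "strand"}
  - {name: "L2", start: 48, end: 50, kind: "loop"}
  - {name: "b3", start: 51, end: 57, kind: "strand"}
  - {name: "L3", start: 58, end: 66, kind: "loop"}
  - {name: "b4", start: 67, end: 73, kind: "strand"}
  - {name: "L4", start: 74, end: 78, kind: "loop"}
  - {name: "b5", start: 79, end: 83, kind: "strand"}
  - {name: "L5", start: 84, end: 86, kind: "loop"}
  - {name: "b6", start: 87, end: 95, kind: "strand"}
  - {name: "L6", start: 96, end: 99, kind: "loop"}
  - {name: "b7", start: 100, end: 109, kind: "strand"}
  - {name: "L7", start: 110, end: 111, kind: "loop"}
  - {name: "b8", start: 112, end: 121, kind: "strand"}
  - {name: "L8", start: 122, end: 127, kind: "loop"}
  - {name: "a1", start: 128, end: 141, kind: "helix"}
  - {name: "L9", start: 142, end: 147, kind: "loop"}
  - {name: "310c", start: 145, end: 147, kind: "310"}
  - {name: "b9", start: 148, end: 150, kind: "strand"}
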