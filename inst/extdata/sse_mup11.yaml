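# Secondary-structure elements of MUP11, mature-protein numbering.
elements:
  - {name: "b1", start: 21, end: 26, kind: "strand"}
  - {name: "L1", start: 27, end: 40, kind: "loop"}
  - {name: "b2", start: 41, end: 47, kind: "strand"}
  - {name: "L2", start: 48, end: 51, kind: "loop"}
  - {name: "b3", start: 52, end: 57, kind: "strand"}
  - {name: "L3", start: 58, end: 65, kind: "loop"}
  - {name: "b4", start: 66, end: 72, kind: "strand"}
  - {name: "L4", start: 73, end: 78, kind: "loop"}
  - {name: "b5", start: 79, end: 82, kind: "strand"}
  - {name: "L5", start: 83, end: 87, kind: "loop"}
  - {name: "b6", start: 88, end: 95, kind: "strand"}
  - {name: "L6", start: 96, end: 99, kind: "loop"}
  - {name: "b7", start: 100, end: 109, kind: "strand"}
  - {name: "L7", start: 110, end: 111, kind: "loop"}
  - {name: "b8", start: 112, end: 121, kind: "strand"}
  - {name: "L8", start: 122, end: 127, kind: "loop"}
  - {name: "a1", start: 128, end: 138, kind: "helix"}
  - {name: "310a", start: 139, end: 141, kind: "310"}
  - {name: "L9", start: 142, end: 147, kind: "loop"}
  - {name: "310b", start: 145, end: 147, kind: "310"}
  - {name: "b9", start: 148, end: 150, kind: "strand"}
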