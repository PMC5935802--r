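# Example beacon map: a two-floor mixed-use office building.
# 17 beacons grouped into 14 areas; beacons sharing an area keep the area's
# id plus a trailing lowercase letter (long corridors, large social areas).
# Area ids: <floor><Kind><counter>, Kind R=room, S=social, C=corridor;
# "Stairs" is a single area serving both floors (one beacon in the well).
# Distances are walking metres between area reference points (door to door).
areas:
  - {id: 1R1, kind: room, floor: 1}
  - {id: 1R2, kind: room, floor: 1}
  - {id: 1R3, kind: room, floor: 1}
  - {id: 1S1, kind: social, floor: 1}
  - {id: 1C1, kind: corridor, floor: 1}
  - {id: 1C2, kind: corridor, floor: 1}
  - {id: 1C3, kind: corridor, floor: 1}
  - {id: Stairs, kind: stairs, floor: both}
  - {id: 2R1, kind: room, floor: 2}
  - {id: 2R2, kind: room, floor: 2}
  - {id: 2S1, kind: social, floor: 2}
  - {id: 2C1, kind: corridor, floor: 2}
  - {id: 2C2, kind: corridor, floor: 2}
  - {id: 2C3, kind: corridor, floor: 2}
beacons:
  - {id: 1R1, area: 1R1, placement: above room door, 20 cm}
  - {id: 1R2, area: 1R2, placement: above room door, 20 cm}
  - {id: 1R3, area: 1R3, placement: above room door, 20 cm}
  - {id: 1S1a, area: 1S1, placement: social area, wall A}
  - {id: 1S1b, area: 1S1, placement: social area, opposing wall B}
  - {id: 1C1a, area: 1C1, placement: long corridor, first straight}
  - {id: 1C1b, area: 1C1, placement: long corridor, second straight}
  - {id: 1C2, area: 1C2, placement: corridor turn}
  - {id: 1C3, area: 1C3, placement: corridor towards stairway}
  - {id: Stairs, area: Stairs, placement: stairwell, serves both floors}
  - {id: 2R1, area: 2R1, placement: above room door, 20 cm}
  - {id: 2R2, area: 2R2, placement: above room door, 20 cm}
  - {id: 2S1a, area: 2S1, placement: social area, wall A}
  - {id: 2S1b, area: 2S1, placement: social area, opposing wall B}
  - {id: 2C1, area: 2C1, placement: corridor from stairway}
  - {id: 2C2, area: 2C2, placement: corridor turn}
  - {id: 2C3, area: 2C3, placement: corridor end}
edges:
  - {from: 1C1, to: 1R1, distance: 6}
  - {from: 1C1, to: 1R2, distance: 6}
  - {from: 1C1, to: 1S1, distance: 7}
  - {from: 1C1, to: 1C2, distance: 10}
  - {from: 1C1, to: 1C3, distance: 9}
  - {from: 1C2, to: 1R3, distance: 6}
  - {from: 1C3, to: Stairs, distance: 7}
  - {from: Stairs, to: 2C1, distance: 7}
  - {from: 2C1, to: 2R1, distance: 6}
  - {from: 2C1, to: 2S1, distance: 7}
  - {from: 2C1, to: 2C2, distance: 9}
  - {from: 2C2, to: 2R2, distance: 6}
  - {from: 2C2, to: 2C3, distance: 8}
  - {from: 2C3, to: 2S1, distance: 8}
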