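# Segment-fixed frame definitions for the four-segment foot model.
# Each segment frame: z = unit(long_axis - origin); x = unit((plane - origin) x z);
# y = z x x; then intrinsic offset rotations rx, ry, rz (degrees) about the
# segment's own x, y, z axes in that order. Frames are right-handed; the rz
# offsets bring every foot segment to the anatomical convention
# (z anterior, y up, x lateral). The left side mirrors the right (rz sign
# flipped for the quarter-turn segments).
right:
  - name: shank
    parent: Global
    origin: V_KneeJC
    long_axis: V_AnkleJC
    plane: LM
    rx: 0
    ry: 0
    rz: 90
  - name: hindfoot
    parent: shank
    origin: BC
    long_axis: V_AnkleJC
    plane: TC
    rx: 0
    ry: 0
    rz: 0
  - name: midfoot
    parent: hindfoot
    origin: V_AnkleJC
    long_axis: TH
    plane: V_MidNC
    rx: 0
    ry: 0
    rz: 180
  - name: forefoot
    parent: midfoot
    origin: V_MidNC
    long_axis: V_15MTH
    plane: NV
    rx: 0
    ry: 0
    rz: -90
  - name: hallux
    parent: forefoot
    origin: MTH1
    long_axis: HLX
    plane: MTH23
    rx: 0
    ry: 0
    rz: 90
left:
  - name: shank
    parent: Global
    origin: V_KneeJC
    long_axis: V_AnkleJC
    plane: LM
    rx: 0
    ry: 0
    rz: -90
  - name: hindfoot
    parent: shank
    origin: BC
    long_axis: V_AnkleJC
    plane: TC
    rx: 0
    ry: 0
    rz: 0
  - name: midfoot
    parent: hindfoot
    origin: V_AnkleJC
    long_axis: TH
    plane: V_MidNC
    rx: 0
    ry: 0
    rz: 180
  - name: forefoot
    parent: midfoot
    origin: V_MidNC
    long_axis: V_15MTH
    plane: NV
    rx: 0
    ry: 0
    rz: 90
  - name: hallux
    parent: forefoot
    origin: MTH1
    long_axis: HLX
    plane: MTH23
    rx: 0
    ry: 0
    rz: -90
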