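# Default full-body model: 15 rigid segments, 42 marker labels, 9 muscles.
# Frames: right-handed, X anterior, Y left, Z up, millimetres.
# Each segment's local origin sits at its proximal joint centre and is
# axis-aligned with the global frame in the neutral standing posture.
# Markers placed exactly at joint centres (ACR, ELB, WRA, KNE, ANK) are
# shared between the adjacent segments' templates; "owns" marks the segment
# that generates the marker's trajectory.
convention:
  handedness: right
  up_axis: z
  units: mm
  frame_indexing: 0-based
stature_mm: 1700
segments:
  pelvis:
    parent: null
    origin: [0, 0, 960]
    sequence: YXZ
    markers:
      ASIS_R: [90, -110, -30]
      ASIS_L: [90, 110, -30]
      PSIS_R: [-110, -45, 0]
      PSIS_L: [-110, 45, 0]
    owns: [ASIS_R, ASIS_L, PSIS_R, PSIS_L]
  upper_trunk:
    parent: pelvis
    joint_offset: [0, 0, 120]
    sequence: YXZ
    markers:
      CLAV: [90, 0, 290]
      XIPH: [105, 0, 170]
      C7: [-60, 0, 320]
      T10: [-80, 0, 90]
      ACR_R: [0, -185, 295]
      ACR_L: [0, 185, 295]
    owns: [CLAV, XIPH, C7, T10, ACR_R, ACR_L]
  head:
    parent: upper_trunk
    joint_offset: [0, 0, 400]
    sequence: YXZ
    markers:
      HEADF_R: [80, -60, 120]
      HEADF_L: [80, 60, 120]
      HEADB_R: [-80, -60, 120]
      HEADB_L: [-80, 60, 120]
    owns: [HEADF_R, HEADF_L, HEADB_R, HEADB_L]
  upper_arm_r:
    parent: upper_trunk
    joint_offset: [0, -185, 295]
    sequence: YXZ
    markers:
      ACR_R: [0, 0, 0]
      UPA_R: [0, -45, -140]
      ELB_R: [0, 0, -285]
    owns: [UPA_R, ELB_R]
  forearm_r:
    parent: upper_arm_r
    joint_offset: [0, 0, -285]
    sequence: YXZ
    markers:
      ELB_R: [0, 0, 0]
      FRA_R: [0, -40, -130]
      WRA_R: [0, 0, -273]
    owns: [FRA_R, WRA_R]
  hand_r:
    parent: forearm_r
    joint_offset: [0, 0, -273]
    sequence: YXZ
    markers:
      WRA_R: [0, 0, 0]
      WRB_R: [0, -30, -10]
      MC3_R: [30, 0, -80]
    owns: [WRB_R, MC3_R]
  upper_arm_l:
    parent: upper_trunk
    joint_offset: [0, 185, 295]
    sequence: YXZ
    markers:
      ACR_L: [0, 0, 0]
      UPA_L: [0, 45, -140]
      ELB_L: [0, 0, -285]
    owns: [UPA_L, ELB_L]
  forearm_l:
    parent: upper_arm_l
    joint_offset: [0, 0, -285]
    sequence: YXZ
    markers:
      ELB_L: [0, 0, 0]
      FRA_L: [0, 40, -130]
      WRA_L: [0, 0, -273]
    owns: [FRA_L, WRA_L]
  hand_l:
    parent: forearm_l
    joint_offset: [0, 0, -273]
    sequence: YXZ
    markers:
      WRA_L: [0, 0, 0]
      WRB_L: [0, 30, -10]
      MC3_L: [30, 0, -80]
    owns: [WRB_L, MC3_L]
  thigh_r:
    parent: pelvis
    joint_offset: [0, -85, -60]
    sequence: YXZ
    markers:
      THI_R: [20, -70, -180]
      THI2_R: [70, -30, -250]
      KNE_R: [0, 0, -415]
    owns: [THI_R, THI2_R, KNE_R]
  shank_r:
    parent: thigh_r
    joint_offset: [0, 0, -415]
    sequence: YXZ
    markers:
      KNE_R: [0, 0, 0]
      SHA_R: [10, -55, -150]
      ANK_R: [0, 0, -419]
    owns: [SHA_R, ANK_R]
  foot_r:
    parent: shank_r
    joint_offset: [0, 0, -419]
    sequence: YXZ
    markers:
      ANK_R: [0, 0, 0]
      HEE_R: [-60, 0, -60]
      MT5_R: [120, -40, -55]
      TOE_R: [180, 10, -50]
    owns: [HEE_R, MT5_R, TOE_R]
  thigh_l:
    parent: pelvis
    joint_offset: [0, 85, -60]
    sequence: YXZ
    markers:
      THI_L: [20, 70, -180]
      THI2_L: [70, 30, -250]
      KNE_L: [0, 0, -415]
    owns: [THI_L, THI2_L, KNE_L]
  shank_l:
    parent: thigh_l
    joint_offset: [0, 0, -415]
    sequence: YXZ
    markers:
      KNE_L: [0, 0, 0]
      SHA_L: [10, 55, -150]
      ANK_L: [0, 0, -419]
    owns: [SHA_L, ANK_L]
  foot_l:
    parent: shank_l
    joint_offset: [0, 0, -419]
    sequence: YXZ
    markers:
      ANK_L: [0, 0, 0]
      HEE_L: [-60, 0, -60]
      MT5_L: [120, 40, -55]
      TOE_L: [180, -10, -50]
    owns: [HEE_L, MT5_L, TOE_L]
muscles:
  rectus_femoris:
    points:
      - {segment: pelvis, xyz: [60, -80, -50]}
      - {segment: shank_r, xyz: [40, 0, -60]}
  vastus_lateralis:
    points:
      - {segment: thigh_r, xyz: [20, -50, -120]}
      - {segment: thigh_r, xyz: [50, -10, -400]}
      - {segment: shank_r, xyz: [40, -10, -50]}
  biceps_femoris:
    points:
      - {segment: pelvis, xyz: [-60, -60, -80]}
      - {segment: shank_r, xyz: [-20, -40, -40]}
  adductor_magnus:
    points:
      - {segment: pelvis, xyz: [0, -20, -90]}
      - {segment: thigh_r, xyz: [0, 55, -350]}
  gracilis:
    points:
      - {segment: pelvis, xyz: [20, -30, -95]}
      - {segment: shank_r, xyz: [0, 45, -40]}
  gluteus_medius:
    points:
      - {segment: pelvis, xyz: [-30, -120, 10]}
      - {segment: thigh_r, xyz: [-10, -35, -25]}
  semimembranosus:
    points:
      - {segment: pelvis, xyz: [-55, -55, -85]}
      - {segment: shank_r, xyz: [-25, 35, -35]}
  pectoralis_major:
    points:
      - {segment: upper_trunk, xyz: [90, -30, 160]}
      - {segment: upper_arm_r, xyz: [15, 5, -60]}
  latissimus_dorsi:
    points:
      - {segment: upper_trunk, xyz: [-80, -20, 60]}
      - {segment: upper_arm_r, xyz: [10, -5, -70]}
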