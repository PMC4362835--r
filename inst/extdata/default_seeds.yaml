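# Default reference seed set: functionally characterized proteins of the
# model phages, one entry per protein class of the head-neck-tail module.
MCP:
  - HK97_gp5
  - T4_gp23
TermL:
  - SPP1_gp2
  - T4_gp17
Portal:
  - SPP1_gp6
  - P22_gp1
  - phi29_gp10
MTP:
  - lambda_gpV
  - T4_gp19
Sheath:
  - T4_gp18
  - phiKZ_sheath
Ad1:
  - SPP1_gp15
Hc1:
  - SPP1_gp16
Tc1:
  - SPP1_gp17
Ne1:
  - SPP1_gp16.1
gpW:
  - lambda_gpW
Ad2:
  - T4_gp13
Hc2:
  - T4_gp14
Tc2:
  - T4_gp15
Ad3:
  - P22_gp4
Hc3:
  - P22_gp10
Ad4:
  - phi29_gp11
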