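species:
- name: DtBP_H
  mz: 192.199999999999989
  mass_u: 192.199999999999989
  charge: 1
  gas_mass_u: 28.013000000000002
  gamma_L: 0.666666666666667
  alpha_2TT: 0.0
  beta_2TT: 0.0
  k0:
    EN_td:
    - 0.0
    - 10.0
    - 20.0
    - 30.0
    - 40.0
    - 50.0
    - 60.0
    - 70.0
    - 80.0
    - 90.0
    - 100.0
    - 110.0
    - 120.0
    - 130.0
    - 140.0
    - 150.0
    - 160.0
    - 170.0
    - 180.0
    - 190.0
    - 200.0
    K0_cm2_Vs:
    - 1.519
    - 1.518683541666666
    - 1.517734166666667
    - 1.516151875
    - 1.513936666666667
    - 1.511088541666667
    - 1.5076075
    - 1.503493541666667
    - 1.498746666666667
    - 1.493366875
    - 1.487354166666667
    - 1.480708541666667
    - 1.47343
    - 1.465518541666667
    - 1.456974166666666
    - 1.447796875
    - 1.437986666666667
    - 1.427543541666667
    - 1.4164675
    - 1.404758541666667
    - 1.392416666666666
reactions: []
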