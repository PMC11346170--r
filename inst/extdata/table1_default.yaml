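n_aided: 63
n_naided: 151
female_fraction:
  AIDED: 0.97
  NAIDED: 0.68
morph_thresholds:
  tortuosity: 1.2
  reflectivity: 2.5
marginals:
  AIDED:
    age:
      family: truncnorm
      mean: 57.008189178209
      sd: 12.098288192429
      lo: 18.0
      hi: 95.0
    osdi_symptoms:
      family: truncnorm
      mean: 13.44153318073
      sd: 4.022178352778
      lo: 0.0
      hi: 20.0
    osdi_vision:
      family: truncnorm
      mean: 8.732129674299
      sd: 4.868031700928
      lo: 0.0
      hi: 20.0
    osdi_triggers:
      family: truncnorm
      mean: 8.207554465711
      sd: 4.068810959391
      lo: 0.0
      hi: 20.0
    osdi_total:
      family: truncnorm
      mean: 71.676242968476
      sd: 22.865637507371
      lo: 0.0
      hi: 100.0
    oxford:
      family: intgrid
      mean: -0.658434378204
      sd: 3.117719558116
      lo: 0.0
      hi: 5.0
    pain:
      family: intgrid
      mean: 3.48463151283
      sd: 3.12605174868
      lo: 0.0
      hi: 10.0
    schirmer_mm:
      family: truncnorm
      mean: -381.785438649829
      sd: 70.990035633558
      lo: 0.0
      hi: 35.0
    tbut_s:
      family: truncnorm
      mean: 1.383142826128
      sd: 4.208983623992
      lo: 0.5
      hi: 20.0
    mean_ic_density:
      family: lognormal
      meanlog: 4.037650875648
      sdlog: 0.394228454033
    mean_nfd:
      family: lognormal
      meanlog: 2.83472375267
      sdlog: 0.5
    mean_tortuosity:
      family: shifted_lognormal
      offset: 1.0
      meanlog: -1.569108624266
      sdlog: 0.6
    mean_reflectivity:
      family: lognormal
      meanlog: 1.372960056293
      sdlog: 0.4
    hla_dr_auf:
      family: lognormal
      meanlog: 10.907044448046
      sdlog: 0.744818031405
  NAIDED:
    age:
      family: truncnorm
      mean: 54.826292049024
      sd: 15.85560486648
      lo: 18.0
      hi: 95.0
    osdi_symptoms:
      family: truncnorm
      mean: 12.000845264454
      sd: 7.115442355966
      lo: 0.0
      hi: 20.0
    osdi_vision:
      family: truncnorm
      mean: 4.155762104214
      sd: 7.509036688002
      lo: 0.0
      hi: 20.0
    osdi_triggers:
      family: truncnorm
      mean: 6.691247012344
      sd: 4.486198288759
      lo: 0.0
      hi: 20.0
    osdi_total:
      family: truncnorm
      mean: 60.1854542088
      sd: 31.539880673094
      lo: 0.0
      hi: 100.0
    oxford:
      family: intgrid
      mean: -31.690516715668
      sd: 6.565882303319
      lo: 0.0
      hi: 5.0
    pain:
      family: intgrid
      mean: 3.48463151283
      sd: 3.12605174868
      lo: 0.0
      hi: 10.0
    schirmer_mm:
      family: truncnorm
      mean: 6.818242459618
      sd: 46.243364149506
      lo: 0.0
      hi: 35.0
    tbut_s:
      family: truncnorm
      mean: 4.868533360898
      sd: 4.800345998126
      lo: 0.5
      hi: 20.0
    mean_ic_density:
      family: lognormal
      meanlog: 3.99956562931
      sdlog: 0.557845539155
    mean_nfd:
      family: lognormal
      meanlog: 2.83472375267
      sdlog: 0.5
    mean_tortuosity:
      family: shifted_lognormal
      offset: 1.0
      meanlog: -1.356385920118
      sdlog: 0.6
    mean_reflectivity:
      family: lognormal
      meanlog: 1.308526771126
      sdlog: 0.4
    hla_dr_auf:
      family: lognormal
      meanlog: 10.838232128644
      sdlog: 0.79751914383
latent_targets:
  variables:
  - age
  - osdi_symptoms
  - osdi_vision
  - osdi_triggers
  - osdi_total
  - oxford
  - pain
  - schirmer_mm
  - tbut_s
  - mean_ic_density
  - mean_nfd
  - mean_tortuosity
  - mean_reflectivity
  - hla_dr_auf
  rows:
    age:
    - 1.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.3
    - 0.25
    - 0.25
    - 0.0
    osdi_symptoms:
    - 0.0
    - 1.0
    - 0.5
    - 0.5
    - 0.75
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    osdi_vision:
    - 0.0
    - 0.5
    - 1.0
    - 0.5
    - 0.75
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    osdi_triggers:
    - 0.0
    - 0.5
    - 0.5
    - 1.0
    - 0.75
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    osdi_total:
    - 0.0
    - 0.75
    - 0.75
    - 0.75
    - 1.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    oxford:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
    - 0.0
    - -0.35
    - -0.3
    - 0.0
    - 0.0
    - 0.25
    - 0.25
    - 0.0
    pain:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    schirmer_mm:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.35
    - 0.0
    - 1.0
    - 0.415823381636
    - 0.0
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    tbut_s:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.3
    - 0.0
    - 0.415823381636
    - 1.0
    - 0.0
    - 0.25
    - 0.0
    - 0.0
    - 0.0
    mean_ic_density:
    - 0.0
    - 0.3
    - 0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 1.0
    - 0.0
    - 0.0
    - 0.0
    - .na.real
    mean_nfd:
    - -0.3
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 0.25
    - 0.0
    - 1.0
    - -0.25
    - 0.0
    - .na.real
    mean_tortuosity:
    - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.25
    - 1.0
    - 0.3
    - .na.real
    mean_reflectivity:
    - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.25
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.3
    - 1.0
    - .na.real
    hla_dr_auf:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - .na.real
    - .na.real
    - .na.real
    - .na.real
    - 1.0
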