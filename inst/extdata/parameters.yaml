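# Fixed model parameters for the methylprednisolone glucose-regulation meta-model.
# Multi-valued entries are keyed by study/arm; the footnote letters of the
# originating parameter tables are retained in comments. All rate constants are per hour unless a
# *_per_day key says otherwise (day-based food-intake parameters are converted to
# hours at load time).

pk:
  iv:                      # IV injection and infusion studies (footnote a)
    CL: 4.91               # clearance, L/h/kg
    Vp: 1.17               # central volume, L/kg
    k12: 0.39              # 1/h
    k21: 0.78              # 1/h
  im:                      # IM injection study (footnote b); shares Vp/k12/k21
    kel: 5.57              # elimination rate constant, 1/h
    Vp: 1.17
    k12: 0.39
    k21: 0.78
    F: 0.214               # bioavailability
    Fr: 0.725              # fraction absorbed via the ka1 pathway
    ka1: 1.255             # 1/h
    ka2: 0.219             # 1/h (flip-flop pathway)

receptor:
  adipose:                 # footnote f; GR mRNA normalized in mol/ng RNA (footnote i)
    kon: 0.016             # 1/nM/h
    kre: 1.31              # 1/h
    Rf: 0.93
    kT: 58.2               # 1/h
    kd_R: 0.05             # 1/h
    kd_Rm: 0.427           # 1/h
    IC50_Rm: 15.6          # fmol/mg protein (DRn scale)
    ks_Rm_raw: 0.416       # printed value; superseded by baseline harmonization
    ks_R_raw: 0.00196      # printed value; superseded by baseline harmonization
    R0: 77.7               # fmol/mg protein
    GRm0:
      im_control: 2050     # footnote a
      default: 2200        # footnotes b-e
  liver:                   # footnote g
    kon: 0.0033
    kre: 0.57
    Rf: 0.49
    kT: 0.63
    kd_R: 0.05             # footnotes f,g
    IC50_Rm: 26.2
    ks_Rm_raw: 2.90        # fmol/g/h; kd_Rm not printed for liver, derived at load
    baselines:
      iv10:     {R0: 420.0, GRm0: 18.6}   # footnote c
      iv50:     {R0: 540.7, GRm0: 25.8}   # footnotes b,d
      im50:     {R0: 540.7, GRm0: 25.8}
      infusion: {R0: 328.7, GRm0: 3.65}   # footnote e
  muscle:                  # footnote h
    kon: 0.0027
    kre: 0.618
    Rf: 0.72
    kT: 58.2               # footnotes f,h
    kd_R: 0.035
    kd_Rm: 0.139
    IC50_Rm: 0.911
    ks_R_raw: 0.777        # printed; superseded by baseline harmonization
    R0: 65.3
    GRm0: 2.99             # fmol/g

leptin:
  kd_Lepm: 0.0427          # 1/h
  S_Lepm: 0.0989           # printed as 1/nM; applied per unit DRn (fmol/mg protein)
  kd_Lep: 4.952            # 1/h
  Lepm0:                   # mol/ng
    im_control: 135600     # footnote a
    im50: 155100           # footnote b
    infusion: 170000       # footnotes c-h
  Lep0:                    # pg/mL
    im_control: 23650
    im50: 25000
    infusion: 5170

food:
  kin_Food0_per_day: 171   # kcal/day^2
  kin_FoodSS_per_day: 147  # kcal/day^2
  Food_max: 57.9           # kcal/day; kout_Food = kin_Food0/Food_max
  IC50_Lep: 11550          # pg/mL
  kFB_per_day: 0.0426      # 1/day
  kd_per_day: 1.21         # 1/day
  Food0:                   # kcal/day at start of study, chronic infusion arms
    saline: 91.7           # footnote c
    "0.03": 80.3           # footnote d
    "0.1": 88.1            # footnote e
    "0.2": 88.5            # footnote f
    "0.3": 94.9            # footnote g
    "0.4": 88.6            # footnote h

liver_cascade:
  kd_C: 0.27               # 1/h
  k1: 0.75                 # 1/h
  kd_Pm: 0.017             # 1/h
  Ss_Pm: 2.11              # (fmol/mg protein)^-1
  Sd_Pm: 2.90              # (fmol/mg protein)^-1
  kd_P: 0.017              # 1/h
  lambda: 0.004            # mRNA -> protein amplification
  Smax_P: 2.11
  SC50_cAMP: 0.0055        # printed fmol/g liver (see vignette on the 1000x ambiguity)
  IC50_cAMP:
    infusion: 433          # footnotes a-f
    injection: 17.8        # footnotes g-k
  cAMP0:                   # pmol/g liver
    infusion: 806          # footnotes a-f
    iv_low: 654            # footnotes g,h (saline IV, 10 mg/kg)
    injection: 656         # footnotes i-k (50 mg/kg IV, IM arms)
  PEPCKm0:                 # fmol/g liver
    infusion: 430
    iv_low: 383
    injection: 209
  PEPCK0:                  # umol ATP/min/g liver
    infusion: 1.83
    injection: 1.4

muscle_cascade:            # IL6R1/IRS-1 mRNA in baseline-relative units
  kd_IL6R1m: 0.306         # 1/h
  Smax_IL6R1m: 3.05
  SC50_IL6R1m: 1.09        # fmol/mg protein (DRn scale)
  ke: 0.144                # 1/h transit rate
  kd_IRS1m: 0.313          # 1/h
  IC50_DRn: 5.95           # fmol/mg protein
  IC50_IL6R1: 0.196        # baseline-relative transit-signal units
  "N": 5                   # transit compartments

systemic:
  kd_G: 0.00521            # 1/h
  S_GI: 0.0305             # (mg/dL)^-1
  S_PEPCK: 0.013           # (umol ATP/min/g liver)^-1
  Smax_cAMP: 3.45
  SC50_cAMPG: 1.82         # pmol/g liver
  S_Food: 0.000346         # (kcal/h)^-1
  lambda1: 1.55
  kd_I: 0.224              # 1/h
  S_IG: 2.87               # (ng/mL)^-1
  S_IF: 0.315              # (ng/mL)^-1, insulin-stimulated FFA disposal
  kd_F: 0.096              # 1/h
  S_FI:                    # (mM)^-1, FFA stimulation of insulin secretion
    acute: 13.3            # single-dose regimens
    chronic: 28.9          # infusion regimens (with exp(-kFI*t) modulation)
  kFI: 0.183               # 1/h
  Smax_F: 15.0
  SC50_F: 2.23             # fmol/mg protein (DRn scale)
  baselines:               # G mg/dL, I ng/mL, FFA mM per study arm
    chronic_infusion:
      saline: {G0: 197, I0: 3.73, FFA0: 0.053}   # a
      "0.03": {G0: 184, I0: 3.45, FFA0: 0.052}   # b
      "0.1":  {G0: 183, I0: 3.57, FFA0: 0.071}   # c
      "0.2":  {G0: 174, I0: 3.97, FFA0: 0.041}   # d
      "0.3":  {G0: 192, I0: 4.90, FFA0: 0.053}   # e
      "0.4":  {G0: 211, I0: 3.89, FFA0: 0.062}   # f
    iv_injection:
      saline: {G0: 119, I0: 1.36, FFA0: 0.055}   # g
      "10":   {G0: 117, I0: 1.00, FFA0: 0.055}   # h
      "50":   {G0: 113, I0: 1.10, FFA0: 0.055}   # i
    short_infusion:
      saline: {G0: 86,  I0: 0.88, FFA0: 0.055}   # j
      "0.1":  {G0: 70,  I0: 1.00, FFA0: 0.055}   # k
      "0.3":  {G0: 80,  I0: 1.00, FFA0: 0.055}   # l
    circadian_nadir:
      saline: {G0: 190, I0: 2.9,  FFA0: 0.12}    # m
      im50:   {G0: 190, I0: 1.5,  FFA0: 0.12}    # n
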