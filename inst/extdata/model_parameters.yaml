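# Kinetic parameters of the four-compartment brain energy metabolism model.
# Keys are ASCII transliterations of the published symbols; units in comments.
# version 1: values as tabulated for the in-vivo human activation scenario.
config_version: 1

# -- volume fractions (dimensionless) and mitochondrial fraction xi
Ve: 0.2
Vcap: 0.0055
Vg: 0.25
Vn: 0.45
xi: 0.07

# -- surface to volume ratios (cm^-1)
SmVn: 2.5e4
SmVg: 2.5e4

# -- physical constants
RTF: 26.73        # RT/F, mV (body temperature)
Faraday: 9.64853e4  # C mol^-1
psi_n: -73.59     # membrane potential, mV
psi_g: -70.0      # mV
Na_e: 150.0       # extracellular sodium, mM

# -- Na,K-ATPase and sodium leak
gNa_n: 0.0136     # mS cm^-2
gNa_g: 0.0061     # mS cm^-2
gKpas: 0.2035     # mS cm^-2 (retained for fidelity; unused in this scenario)
kpump_n: 2.2e-6   # cm mM^-1 s^-1
kpump_g: 4.5e-7   # cm mM^-1 s^-1
Jpump0_g: 0.0687  # mM s^-1 (astrocytic pump offset)
Km_pump: 0.5      # mM

# -- glucose transport (Tmax mM s^-1, Kt mM)
Tmax_GLC_en: 0.041
Tmax_GLC_ce: 0.239
Tmax_GLC_eg: 0.147
Tmax_GLC_cg: 0.0016
Kt_GLC_en: 8.0
Kt_GLC_eg: 8.0
Kt_GLC_cg: 8.0
Kt_GLC_ce: 8.0    # not tabulated separately; all printed glucose affinities are 8 mM

# -- hexokinase-phosphofructokinase lump
kHKPFK_n: 0.0504  # s^-1
kHKPFK_g: 0.185   # s^-1
KI_ATP: 1.0       # mM
nH: 4.0
Kg: 0.05          # mM

# -- phosphoglycerate kinase (mM^-1 s^-1)
kPGK_n: 3.97
kPGK_g: 135.2

# -- pyruvate kinase (mM^-1 s^-1)
kPK_n: 36.7
kPK_g: 401.7

# -- lactate dehydrogenase (L mmol^-1 s^-1)
kLDHp_n: 72.3
kLDHp_g: 1.59
kLDHm_n: 0.72
kLDHm_g: 0.071

# -- lactate transport (Tmax mM s^-1, Kt mM)
Tmax_LAC_gc: 0.00243
Tmax_LAC_ne: 24.3
Tmax_LAC_ge: 106.1
Tmax_LAC_ec: 0.25
Kt_LAC_ne: 0.74
Kt_LAC_ge: 3.5
Kt_LAC_gc: 1.0
Kt_LAC_ec: 1.0

# -- TCA cycle influx
Vmax_in_n: 0.1303 # mM s^-1
Vmax_in_g: 5.7    # mM s^-1
Km_mito: 0.04     # mM
Km_NAD_n: 0.409   # mM
Km_NAD_g: 40.3    # mM

# -- electron transport chain
Km_ADP_n: 3.41e-3 # mM
Km_ADP_g: 0.483e-3
Km_NADH_n: 4.44e-2
Km_NADH_g: 2.69e-2
KO2_mito: 0.001   # mM
Vmax_out_n: 0.164 # mM s^-1
Vmax_out_g: 0.064 # mM s^-1

# -- NADH shuttles
Mcyto_n: 4.9e-8
Mcyto_g: 2.5e-4
Mmito_n: 3.93e5
Mmito_g: 1.06e4
TNADH_n: 10330.0  # mM s^-1
TNADH_g: 150.0    # mM s^-1

# -- creatine pool and creatine kinase
C_tot: 10.0       # total creatine + phosphocreatine, mM
kCKp_n: 0.0433    # mM^-1 s^-1
kCKp_g: 0.00135
kCKm_n: 2.8e-4
kCKm_g: 1.0e-5

# -- oxygen exchange
KO2: 0.0361       # mM
HbOP: 8.6         # mM
nh_O2: 2.73
PScapVn: 1.66     # s^-1
PScapVg: 0.87     # s^-1

# -- arterial concentrations (mM)
O2_a: 8.35
GLC_a: 4.75
LAC_a: 0.506

# -- venous balloon
tau_v: 35.0       # s
alpha_v: 0.5

# -- conserved pools
N_tot: 0.212      # total NAD pool, mM
A_tot: 2.212      # total adenine nucleotide pool, mM
qAK: 0.92         # adenylate kinase equilibrium constant

# -- ATPase offsets (mM s^-1)
JATPases_n: 0.1695
JATPases_g: 0.1404

# -- haemodynamics / BOLD
F0: 0.012         # baseline cerebral blood flow, s^-1
k1: 2.22
k2: 0.46
k3: 0.43
Vv0: 0.02         # baseline venous volume fraction
dHb0: 0.058       # baseline deoxyhemoglobin, mM
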