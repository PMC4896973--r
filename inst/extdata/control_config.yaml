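# Control configuration for the three-node ocellar GRN.
#
# The gradient parameters give a Hh decay length ell = sqrt(D/beta_Hh)
# of about 19 um; alpha_Hh is set so the saturated source concentration
# alpha_Hh/beta_Hh = 1 defines the concentration unit.  Intracellular
# rates are in scaled units (degradation rates set the time unit); only
# the steady state is analyzed.  This set yields the reference
# OC-IOC-OC pattern: a central En (IOC) domain over the Hh source
# flanked by two CiA (OC) domains.
gradient:
  alpha_Hh: 2.3e-4      # Hh production in the source (conc s^-1)
  beta_Hh: 2.3e-4       # Hh turnover (s^-1)
  D: 0.085              # effective Hh diffusion (um^2 s^-1)
  omega: 30.0           # Hh source width (um)
intracellular:
  alpha_PtcHh: 1.0      # basal Hh-driven PtcHh complex formation
  alpha_CiA: 1.8        # maximal PtcHh-driven CiA production
  alpha_En: 8.0        # maximal CiA-driven En production
  beta_PtcHh: 1.0
  beta_CiA: 1.0
  beta_En: 3.0          # En tracks CiA quasi-statically
  alpha_CiA_PtcHh: 3.0  # CiA -> PtcHh positive feedback strength
  alpha_En_PtcHh: 2.0   # En repression weight on PtcHh production
  alpha_En_CiA: 0.5     # En repression weight on CiA production
  alpha_En_En: 6.0      # En self-maintenance rate above zeta_En
  k_PtcHh: 1.0          # half-saturation of the CiA -> PtcHh feedback
  k_CiA: 0.85           # Hill constant, PtcHh activating CiA
  k_En: 1.15            # Hill constant, CiA activating En (low sensitivity)
  n_CiA: 1.5            # Hill coefficient, PtcHh -> CiA
  n_En: 4.0             # Hill coefficient, CiA -> En
  zeta_En: 0.22         # En self-maintenance threshold
grid:
  half_length: 100.0    # um to each side of the source centre
  dx: 1.0               # um
solver:
  stop_tol: 0.01        # Norm-2 stop criterion on raw profiles
  check_every: 100      # steps between convergence checks
  max_steps: 200000
# Literature ranges for the Hh gradient parameters used by the extended
# morphospace (D in um^2 s^-1; beta_Hh in s^-1).  The published medium
# and bad ranges for D are garbled (identical and reversed), so they are
# reconstructed below the good range with the same relative widths as the
# beta_Hh tiers.
gradient_tiers:
  D:
    good: [0.068, 0.109]
    medium: [0.043, 0.068]
    bad: [0.027, 0.043]
  beta_Hh:
    good: [2.1e-4, 2.5e-4]
    medium: [1.5e-4, 2.1e-4]
    bad: [1.0e-4, 1.5e-4]
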