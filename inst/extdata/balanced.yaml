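# Plastic balanced random network: bundled literature defaults.
#
# Population sizes, the ~0.1 connection probability and the initial
# weights (excitatory 0.04561 nA, inhibitory -0.22805 nA) are the
# benchmark values this package reproduces. Neuron, drive and STDP rule
# constants not restated there follow the published description of the
# source model (Morrison, Aertsen & Diesmann 2007, sections 3 and 4.1):
# power-law STDP with mu = 0.4 and a reference weight chosen so the
# rule's uncorrelated-balance fixed point w0 * alpha^(-1/(1-mu)) sits at
# the initial excitatory weight (the source model starts at its
# equilibrium). The external drive rate was fixed once, by mean-field
# reasoning plus short pilot runs, to place the network in an
# asynchronous-irregular regime near 9 Hz.

dt_ms: 0.1

populations:
  n_exc: 90000
  n_inh: 22500

neuron:
  tau_m_ms: 10.0
  c_m_pf: 250.0          # r_m = 40 MOhm
  v_rest_mv: -70.0
  v_thresh_mv: -50.0
  v_reset_mv: -70.0
  tau_ref_ms: 0.5
  tau_syn_ms: 0.33       # alpha-synapse time constant
  v_init_mean_mv: -60.0
  v_init_sd_mv: 5.0

connectivity:
  p_conn: 0.1
  delay_ms: 1.0

weights:
  exc_init_na: 0.04561
  inh_init_na: -0.22805

stdp:                     # excitatory -> excitatory only
  lambda: 0.1
  alpha: 0.1
  mu: 0.4
  tau_ms: 20.0
  w0_na: 0.001            # 1 pA reference weight

external:
  # Poisson events per neuron per second (excitatory, weight = exc_init)
  rate_hz: 45000.0
  weight_na: 0.04561
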