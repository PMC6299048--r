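# Layered cortical microcircuit: bundled literature defaults.
#
# Population sizes, the connection-probability table, neuron parameters,
# external in-degrees and delay distributions follow the published
# description of the source model (Potjans & Diesmann 2014, Tables 4-5);
# the synaptic weight statistics are the ones restated in the benchmark
# description this package reproduces (excitatory 0.0878 +/- 0.00878 nA,
# inhibitory -0.3512 +/- 0.03512 nA, L4e->L2/3e doubled). The
# reference_rates_hz block holds published full-scale stationary rates and
# is used only for the DC compensation applied when downscaling.

dt_ms: 0.1

populations:
  names: [L23e, L23i, L4e, L4i, L5e, L5i, L6e, L6i]
  sizes: [20683, 5834, 21915, 5479, 4850, 1065, 14395, 2948]

neuron:
  tau_m_ms: 10.0
  c_m_pf: 250.0          # r_m = tau_m / c_m = 40 MOhm
  v_rest_mv: -65.0
  v_thresh_mv: -50.0
  v_reset_mv: -65.0
  tau_ref_ms: 2.0
  tau_syn_ms: 0.5
  v_init_mean_mv: -58.0
  v_init_sd_mv: 10.0

# conn_prob[target][source]: probability that a given (source, target)
# pair is connected; converted to a total synapse count with the
# pairwise-Bernoulli convention of the source model.
conn_prob:
  L23e: {L23e: 0.1009, L23i: 0.1689, L4e: 0.0437, L4i: 0.0818, L5e: 0.0323, L5i: 0.0,    L6e: 0.0076, L6i: 0.0}
  L23i: {L23e: 0.1346, L23i: 0.1371, L4e: 0.0316, L4i: 0.0515, L5e: 0.0755, L5i: 0.0,    L6e: 0.0042, L6i: 0.0}
  L4e:  {L23e: 0.0077, L23i: 0.0059, L4e: 0.0497, L4i: 0.135,  L5e: 0.0067, L5i: 0.0003, L6e: 0.0453, L6i: 0.0}
  L4i:  {L23e: 0.0691, L23i: 0.0029, L4e: 0.0794, L4i: 0.1597, L5e: 0.0033, L5i: 0.0,    L6e: 0.1057, L6i: 0.0}
  L5e:  {L23e: 0.1004, L23i: 0.0622, L4e: 0.0505, L4i: 0.0057, L5e: 0.0831, L5i: 0.3726, L6e: 0.0204, L6i: 0.0}
  L5i:  {L23e: 0.0548, L23i: 0.0269, L4e: 0.0257, L4i: 0.0022, L5e: 0.06,   L5i: 0.3158, L6e: 0.0086, L6i: 0.0}
  L6e:  {L23e: 0.0156, L23i: 0.0066, L4e: 0.0211, L4i: 0.0166, L5e: 0.0572, L5i: 0.0197, L6e: 0.0396, L6i: 0.2252}
  L6i:  {L23e: 0.0364, L23i: 0.001,  L4e: 0.0034, L4i: 0.0005, L5e: 0.0277, L5i: 0.008,  L6e: 0.0658, L6i: 0.1443}

weights:
  exc_mean_na: 0.0878
  exc_sd_na: 0.00878
  inh_mean_na: -0.3512
  inh_sd_na: 0.03512
  # deviating connection marked in the wiring diagram: L4e -> L2/3e is
  # doubled relative to the common excitatory mean (read from the figure).
  l4e_to_l23e_mean_na: 0.1756
  l4e_to_l23e_sd_na: 0.00878

delays:
  exc_mean_ms: 1.5
  exc_sd_ms: 0.75
  inh_mean_ms: 0.75
  inh_sd_ms: 0.375

external:
  nu_ext_hz: 8.0
  weight_na: 0.0878
  # in-degrees of the Poisson background per population
  k_ext: [1600, 1500, 2100, 1900, 2000, 1900, 2900, 2100]

# Published full-scale stationary rates (Hz), used only to compute the
# mean-input DC compensation under downscaling.
reference_rates_hz: [0.85, 2.97, 4.45, 5.93, 7.59, 8.64, 1.09, 7.66]
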