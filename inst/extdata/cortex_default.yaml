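# Default layered cortical circuit: 17 neuronal groups, 10,000 neurons
# (8000 excitatory / 2000 inhibitory). Every ordered pair of groups is
# wired at sparseness 0.1 with weight 10 mV; thalamic Gaussian noise
# drives layers L2/3, L4 and L6.
groups:
  - {name: RS_p2,    cell_class: pyramidal, layer: L2/3, count: 2500, spiking_type: RS,  receptor: AMPA}
  - {name: RS_p4,    cell_class: pyramidal, layer: L4,   count: 1000, spiking_type: RS,  receptor: AMPA}
  - {name: CH_p2,    cell_class: pyramidal, layer: L2/3, count: 500,  spiking_type: CH,  receptor: AMPA}
  - {name: IB_p5_1,  cell_class: pyramidal, layer: L5/6, count: 100,  spiking_type: IB,  receptor: NMDA}
  - {name: CH_p4,    cell_class: pyramidal, layer: L4,   count: 1400, spiking_type: CH,  receptor: AMPA}
  - {name: IB_p5_2,  cell_class: pyramidal, layer: L5/6, count: 500,  spiking_type: IB,  receptor: NMDA}
  - {name: RS_ss4_1, cell_class: spiny,     layer: L4,   count: 1000, spiking_type: RS,  receptor: AMPA}
  - {name: RS_ss4_2, cell_class: spiny,     layer: L2/3, count: 1000, spiking_type: RS,  receptor: AMPA}
  - {name: LTS_nb1,  cell_class: GABA_nb,   layer: L1,   count: 200,  spiking_type: LTS, receptor: GABA}
  - {name: LTS_nb2,  cell_class: GABA_nb,   layer: L2,   count: 400,  spiking_type: LTS, receptor: GABA}
  - {name: LTS_nb4,  cell_class: GABA_nb,   layer: L4,   count: 200,  spiking_type: LTS, receptor: GABA}
  - {name: LTS_nb5,  cell_class: GABA_nb,   layer: L5,   count: 100,  spiking_type: LTS, receptor: GABA}
  - {name: LTS_nb6,  cell_class: GABA_nb,   layer: L6,   count: 200,  spiking_type: LTS, receptor: GABA}
  - {name: FS_b2,    cell_class: GABA_b,    layer: L2,   count: 200,  spiking_type: FS,  receptor: GABA}
  - {name: FS_b4,    cell_class: GABA_b,    layer: L4,   count: 400,  spiking_type: FS,  receptor: GABA}
  - {name: FS_b5,    cell_class: GABA_b,    layer: L5,   count: 100,  spiking_type: FS,  receptor: GABA}
  - {name: FS_b6,    cell_class: GABA_b,    layer: L6,   count: 200,  spiking_type: FS,  receptor: GABA}
connections:
  rule: all_pairs
  sparseness: 0.1
  weight: 10
noise:
  target_layers: ["L2/3", "L4", "L6"]
  sigma_exc: 5
  sigma_inh: 2
synapse:
  tau_ampa: 5
  tau_nmda: 150
  tau_gaba: 10
  coupling: current    # g enters I additively (GABA subtracts)
  g_init_max: 1
  scale: indegree      # recurrent drive normalised by synapse count
  gain: 1.5            # dimensionless gain on the scaled drive
plasticity:
  enabled: false
  eta: 0.01
  epoch_ms: 50
run:
  duration: 150
  dt: 0.5
  seed: 1
expect_composition:
  excitatory: 0.8
  inhibitory: 0.2
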