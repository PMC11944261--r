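# Default parameter sets for the five rule-based visual-field criteria,
# expressed in the generic cluster-rule engine's vocabulary. These are
# editable reconstructions of the published criteria restricted to their
# visual-field component; levels name normative probability categories.
# map: which deviation probability map the rule reads (TD or PD).
LoGTS:
  map: TD
  cluster_min_size: 3
  cluster_level: "p<2%"
  anchor_level: "p<1%"
  non_edge_only: false
  same_hemifield: true
  require_ght_outside: false
  require_psd_abnormal: false
  psd_percentile: 0.95
  confirmation_tests: 1
UKGTS:
  map: TD
  cluster_min_size: 2
  cluster_level: "p<1%"
  anchor_level: "p<1%"
  non_edge_only: false
  same_hemifield: false
  require_ght_outside: false
  require_psd_abnormal: false
  psd_percentile: 0.95
  confirmation_tests: 1
Kang:
  map: TD
  cluster_min_size: 3
  cluster_level: "p<5%"
  anchor_level: "p<1%"
  non_edge_only: true
  same_hemifield: true
  require_ght_outside: false
  require_psd_abnormal: false
  psd_percentile: 0.95
  confirmation_tests: 1
HAP2_p1:
  map: PD
  cluster_min_size: 3
  cluster_level: "p<5%"
  anchor_level: "p<1%"
  non_edge_only: true
  same_hemifield: false
  require_ght_outside: false
  require_psd_abnormal: false
  psd_percentile: 0.95
  confirmation_tests: 1
Foster:
  map: PD
  cluster_min_size: 3
  cluster_level: "p<5%"
  anchor_level: "p<5%"
  non_edge_only: false
  same_hemifield: false
  require_ght_outside: true
  require_psd_abnormal: false
  psd_percentile: 0.95
  confirmation_tests: 1
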