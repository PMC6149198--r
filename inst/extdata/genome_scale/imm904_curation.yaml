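# Editable curation recipe template for the iMM904 genome-scale model of
# Saccharomyces cerevisiae. The published analysis this pipeline follows
# curated iMM904 by constraining reversibility of some reactions,
# inactivating some reactions and adding transport reactions for cofactor
# utilization, for a curated total of 1581 reactions; the exact edit list is
# not enumerated in the main text, so this file is a best-effort placeholder
# the user is expected to edit. The reaction count after curation is a
# recipe-dependent check, not an assertion of this package.
reversibility: []
deactivate: []
add_transport:
  # Example cofactor transport additions (edit ids/metabolites to match the
  # model file actually in use; BiGG namespace assumed):
  - id: NADHt_cm_added
    metabolites: {nadh_c: -1, nadh_m: 1}
    lower_bound: 0
    upper_bound: 1000
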