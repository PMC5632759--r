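# Bundled example data

`kb_peptides.csv`, `kb_network_edges.csv` — an H-2Kb-restricted
cross-reactivity network of vaccinia / LCMV / pichinde virus octamer
epitopes, transcribed from the published primary literature on
heterologous immunity in these systems. The edge list is an illustrative
reconstruction of the reported assay outcomes (direction = priming line
-> recognized target; `none` = tested, not cross-reactive), not a
complete record of every experiment.
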