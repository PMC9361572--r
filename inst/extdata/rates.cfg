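# Neutral substitution rates (substitutions/site/year) and lineage map
within_clade_rate=5.2e-9
cross_clade_rate=1.5e-8
clade.celery=apiaceae
clade.coriander=apiaceae
clade.carrot=apiaceae
clade.arabidopsis=rosid
clade.grape=rosid
clade.lettuce=asterid
clade.ginseng=asterid
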