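field,concept_id,unit_concept_id
global_rnfl_thickness,2000000001,8749
superior_rnfl_thickness,2000000002,8749
inferior_rnfl_thickness,2000000003,8749
total_macular_volume,2000000004,2000000101
central_macular_thickness,2000000005,8749
prev_total_macular_volume,2000000006,2000000101
prev_central_macular_thickness,2000000007,8749
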