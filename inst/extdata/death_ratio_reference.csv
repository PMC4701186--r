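site,deaths_neonatal,deaths_infant,deaths_under5,nn_infant_rmm,nn_infant_fph,infant_u5_rmm,infant_u5_fph
ethiopia,125,188,244,66.5,61.0,77.0,68.4
malawi,87,142,265,61.2,52.6,53.5,61.3
mali,53,106,179,50.0,46.1,59.2,49.8
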