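sample_id,predicted,true
Patient #2,Ben,Ben
Patient #9,PTC,PTC
Patient #13,Ben,Ben
Patient #14,PTC,PTC
Patient #18,PTC,PTC
Patient #20,PTC,Ben
Patient #22,Ben,Ben
Patient #34,Ben,Ben
Patient #36,Ben,Ben
Patient #37,Ben,Ben
Patient #41,PTC,Ben
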