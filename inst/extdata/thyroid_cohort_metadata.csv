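patient_id,cytological_class,histological_class
Patient #1,THY2,Ben
Patient #2,THY3,Ben
Patient #3,THY4,PTC
Patient #4,THY5,PTC
Patient #5,THY2,Ben
Patient #6,THY5,PTC
Patient #7,THY2,Ben
Patient #8,THY5,PTC
Patient #9,THY3,PTC
Patient #10,THY4,PTC
Patient #11,THY2,Ben
Patient #12,THY4,PTC
Patient #13,THY3,Ben
Patient #14,THY3,PTC
Patient #15,THY4,PTC
Patient #16,THY2,Ben
Patient #17,THY2,Ben
Patient #18,THY3,PTC
Patient #19,THY2,Ben
Patient #20,THY3,Ben
Patient #21,THY4,PTC
Patient #22,THY3,Ben
Patient #23,THY5,PTC
Patient #24,THY2,Ben
Patient #25,THY4,PTC
Patient #26,THY4,PTC
Patient #27,THY2,Ben
Patient #28,THY2,Ben
Patient #29,THY2,Ben
Patient #30,THY5,PTC
Patient #31,THY5,PTC
Patient #32,THY2,Ben
Patient #33,THY5,PTC
Patient #34,THY3,Ben
Patient #35,THY2,Ben
Patient #36,THY3,Ben
Patient #37,THY3,Ben
Patient #38,THY5,PTC
Patient #39,THY5,PTC
Patient #40,THY5,PTC
Patient #41,THY3,Ben
Patient #42,THY4,PTC
Patient #43,THY2,Ben
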