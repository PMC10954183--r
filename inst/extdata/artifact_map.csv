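grain_id,artifact
Ala 0002,0316-1
Ala 0004,0316-1
Ala 0005,0316-1
Ala 0006,0316-1
Ala 0007,0316-1
Ala 0010,0316-1
Ala 0011,0316-2
Ala 0012,0316-2
Ala 0013,0316-2
Ala 0014,0316-3
Ala 0015,0316-3
Ala 0016,0316-3
Ala 0021,0316-4
Ala 0023,0316-4
Ala 0024,0316-4
Ala 0027,0316-6
Ala 0037,0322-1
Ala 0039,0322-2
Ala 0041,0322-2
Ala 0043,0322-3
Ala 0044,0322-3
Ala 0045,0322-3
Ala 0046,0322-3
Ala 0047,0322-4
Ala 0048,0322-4
Ala 0049,0322-4
Ala 0050,0322-4
Ala 0051,0322-4
Ala 0052,0322-4
Ala 0053,0322-4
Ala 0055,0322-5
Ala 0056,0322-5
Ala 0057,0322-5
Ala 0058,0322-6
Ala 0060,0322-7
Ala 0061,0322-7
Ala 0063,0322-7
Ala 0064,0322-7
Ala 0065,0322-7
Ala 0066,0322-7
Ala 0071,0322-8
Ala 0072,0322-9
Ala 0073,0322-9
Ala 0074,0322-9
Ala 0075,0322-9
Ala 0077,0322-11
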