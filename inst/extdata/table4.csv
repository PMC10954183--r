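artifact,artifact_type,n_grains
0316-1,non-retouched flake,6
0316-2,non-retouched flake,3
0316-3,non-retouched flake,3
0316-4,non-retouched flake,3
0316-5,non-retouched flake,0
0316-6,non-retouched flake,1
0316-7,non-retouched flake,0
0316-8,non-retouched flake,0
0316-9,non-retouched flake,0
0322-1,non-retouched flake,1
0322-2,non-retouched flake,2
0322-3,non-retouched flake,4
0322-4,non-retouched flake,7
0322-5,non-retouched flake,3
0322-6,non-retouched flake,1
0322-7,non-retouched flake,6
0322-8,non-retouched flake,1
0322-9,non-retouched flake,4
0322-10,non-retouched flake,0
0322-11,non-retouched flake,1
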