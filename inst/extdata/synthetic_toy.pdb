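ATOM      1  CA  ALA A   1       5.173   3.417  -4.642  1.00  0.00              
ATOM      2  CA  ALA A   2      -0.151  -6.401  -4.732  1.00  0.00              
ATOM      3  CA  ALA A   3       2.989   0.676  -1.823  1.00  0.00              
ATOM      4  CA  ALA A   4      -0.798  -4.313   0.056  1.00  0.00              
ATOM      5  CA  ALA A   5       1.506  -2.356   6.769  1.00  0.00              
ATOM      6  CA  ALA A   6      -3.316  -4.587  -6.631  1.00  0.00              
ATOM      7  CA  ALA A   7       7.607   1.473  -0.297  1.00  0.00              
ATOM      8  CA  ALA A   8      -2.566  -4.363   6.532  1.00  0.00              
ATOM      9  CA  ALA A   9       5.760   1.953   4.754  1.00  0.00              
ATOM     10  CA  ALA A  10      -3.529  -7.704  -1.650  1.00  0.00              
ATOM     11  CA  ALA A  11      -0.882   3.904   0.457  1.00  0.00              
ATOM     12  CA  ALA A  12      -5.891  -0.155  -1.172  1.00  0.00              
ATOM     13  CA  ALA A  13      -5.025   3.308   4.958  1.00  0.00              
ATOM     14  CA  ALA A  14      -2.586   1.084  -3.454  1.00  0.00              
ATOM     15  CA  ALA A  15       6.295  -2.979   2.388  1.00  0.00              
ATOM     16  CA  ALA A  16       2.018   0.132  -8.223  1.00  0.00              
ATOM     17  CA  ALA A  17       1.050   3.929  -3.341  1.00  0.00              
ATOM     18  CA  ALA A  18      -2.531   1.129   8.225  1.00  0.00              
ATOM     19  CA  ALA A  19       0.185   1.590   4.777  1.00  0.00              
ATOM     20  CA  ALA A  20       0.907   7.896  -3.214  1.00  0.00              
ATOM     21  CA  ALA A  21      -2.890   4.645  -4.928  1.00  0.00              
ATOM     22  CA  ALA A  22      -6.123  -5.051  -3.523  1.00  0.00              
ATOM     23  CA  ALA A  23      -6.584  -0.567   4.274  1.00  0.00              
ATOM     24  CA  ALA A  24       4.146   6.473  -0.695  1.00  0.00              
ATOM     25  CA  ALA A  25       2.133  -0.387   2.017  1.00  0.00              
END   
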