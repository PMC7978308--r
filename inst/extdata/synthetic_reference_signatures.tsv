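# synthetic toy reference signature catalog (NOT COSMIC); generated by synthetic_reference_signatures()
channel	SBS1_like	SBS5_like	SBS4_like	SBS22_like	SBS40_like
A[C>A]A	0.003125	0.00892857	0.0338542	0.00173611	0.013535
A[C>A]C	0.003125	0.00892857	0.0338542	0.00173611	0.0135149
A[C>A]G	0.003125	0.00892857	0.0338542	0.00173611	0.0134816
A[C>A]T	0.003125	0.00892857	0.0338542	0.00173611	0.0134352
C[C>A]A	0.003125	0.00892857	0.0651042	0.00173611	0.0133758
C[C>A]C	0.003125	0.00892857	0.0651042	0.00173611	0.0133038
C[C>A]G	0.003125	0.00892857	0.0651042	0.00173611	0.0132194
C[C>A]T	0.003125	0.00892857	0.0651042	0.00173611	0.013123
G[C>A]A	0.003125	0.00892857	0.0338542	0.00173611	0.013015
G[C>A]C	0.003125	0.00892857	0.0338542	0.00173611	0.0128959
G[C>A]G	0.003125	0.00892857	0.0338542	0.00173611	0.0127662
G[C>A]T	0.003125	0.00892857	0.0338542	0.00173611	0.0126264
T[C>A]A	0.003125	0.00892857	0.0651042	0.00173611	0.0124771
T[C>A]C	0.003125	0.00892857	0.0651042	0.00173611	0.012319
T[C>A]G	0.003125	0.00892857	0.0651042	0.00173611	0.0121528
T[C>A]T	0.003125	0.00892857	0.0651042	0.00173611	0.0119792
A[C>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.0117988
A[C>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.0116126
A[C>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.0114212
A[C>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.0112255
C[C>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.0110263
C[C>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.0108246
C[C>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.0106211
C[C>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.0104167
G[C>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.0102123
G[C>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.0100088
G[C>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.00980701
G[C>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.00960786
T[C>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.00941217
T[C>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.00922078
T[C>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.00903451
T[C>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.00885417
A[C>T]A	0.0114583	0.0133929	0.00260417	0.00173611	0.00868051
A[C>T]C	0.0114583	0.0133929	0.00260417	0.00173611	0.00851429
A[C>T]G	0.153125	0.0133929	0.00260417	0.00173611	0.00835621
A[C>T]T	0.0114583	0.0133929	0.00260417	0.00173611	0.00820696
C[C>T]A	0.0114583	0.0133929	0.00260417	0.00173611	0.00806717
C[C>T]C	0.0114583	0.0133929	0.00260417	0.00173611	0.00793744
C[C>T]G	0.153125	0.0133929	0.00260417	0.00173611	0.00781832
C[C>T]T	0.0114583	0.0133929	0.00260417	0.00173611	0.00771034
G[C>T]A	0.0114583	0.0133929	0.00260417	0.00173611	0.00761394
G[C>T]C	0.0114583	0.0133929	0.00260417	0.00173611	0.00752954
G[C>T]G	0.153125	0.0133929	0.00260417	0.00173611	0.00745751
G[C>T]T	0.0114583	0.0133929	0.00260417	0.00173611	0.00739815
T[C>T]A	0.0114583	0.0133929	0.00260417	0.00173611	0.00735171
T[C>T]C	0.0114583	0.0133929	0.00260417	0.00173611	0.0073184
T[C>T]G	0.153125	0.0133929	0.00260417	0.00173611	0.00729836
T[C>T]T	0.0114583	0.0133929	0.00260417	0.00173611	0.00729167
A[T>A]A	0.003125	0.00892857	0.00260417	0.0313657	0.00729836
A[T>A]C	0.003125	0.00892857	0.00260417	0.0313657	0.0073184
A[T>A]G	0.003125	0.00892857	0.00260417	0.0313657	0.00735171
A[T>A]T	0.003125	0.00892857	0.00260417	0.0313657	0.00739815
C[T>A]A	0.003125	0.00892857	0.00260417	0.0313657	0.00745751
C[T>A]C	0.003125	0.00892857	0.00260417	0.0313657	0.00752954
C[T>A]G	0.003125	0.00892857	0.00260417	0.390625	0.00761394
C[T>A]T	0.003125	0.00892857	0.00260417	0.0313657	0.00771034
G[T>A]A	0.003125	0.00892857	0.00260417	0.0313657	0.00781832
G[T>A]C	0.003125	0.00892857	0.00260417	0.0313657	0.00793744
G[T>A]G	0.003125	0.00892857	0.00260417	0.0313657	0.00806717
G[T>A]T	0.003125	0.00892857	0.00260417	0.0313657	0.00820696
T[T>A]A	0.003125	0.00892857	0.00260417	0.0313657	0.00835621
T[T>A]C	0.003125	0.00892857	0.00260417	0.0313657	0.00851429
T[T>A]G	0.003125	0.00892857	0.00260417	0.0313657	0.00868051
T[T>A]T	0.003125	0.00892857	0.00260417	0.0313657	0.00885417
A[T>C]A	0.003125	0.0133929	0.00260417	0.00173611	0.00903451
A[T>C]C	0.003125	0.0133929	0.00260417	0.00173611	0.00922078
A[T>C]G	0.003125	0.0133929	0.00260417	0.00173611	0.00941217
A[T>C]T	0.003125	0.0133929	0.00260417	0.00173611	0.00960786
C[T>C]A	0.003125	0.0133929	0.00260417	0.00173611	0.00980701
C[T>C]C	0.003125	0.0133929	0.00260417	0.00173611	0.0100088
C[T>C]G	0.003125	0.0133929	0.00260417	0.00173611	0.0102123
C[T>C]T	0.003125	0.0133929	0.00260417	0.00173611	0.0104167
G[T>C]A	0.003125	0.0133929	0.00260417	0.00173611	0.0106211
G[T>C]C	0.003125	0.0133929	0.00260417	0.00173611	0.0108246
G[T>C]G	0.003125	0.0133929	0.00260417	0.00173611	0.0110263
G[T>C]T	0.003125	0.0133929	0.00260417	0.00173611	0.0112255
T[T>C]A	0.003125	0.0133929	0.00260417	0.00173611	0.0114212
T[T>C]C	0.003125	0.0133929	0.00260417	0.00173611	0.0116126
T[T>C]G	0.003125	0.0133929	0.00260417	0.00173611	0.0117988
T[T>C]T	0.003125	0.0133929	0.00260417	0.00173611	0.0119792
A[T>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.0121528
A[T>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.012319
A[T>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.0124771
A[T>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.0126264
C[T>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.0127662
C[T>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.0128959
C[T>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.013015
C[T>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.013123
G[T>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.0132194
G[T>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.0133038
G[T>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.0133758
G[T>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.0134352
T[T>G]A	0.003125	0.00892857	0.00260417	0.00173611	0.0134816
T[T>G]C	0.003125	0.00892857	0.00260417	0.00173611	0.0135149
T[T>G]G	0.003125	0.00892857	0.00260417	0.00173611	0.013535
T[T>G]T	0.003125	0.00892857	0.00260417	0.00173611	0.0135417
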