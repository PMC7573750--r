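metric	performance	experiment	score
fisher	precision	brain	0.442
sobolev	precision	brain	0.462
clark	precision	brain	0.435
bhattacharyya	precision	brain	0.434
soergel	precision	brain	0.45
hassanat	precision	brain	0.462
euclidean	precision	brain	0.461
manhattan	precision	brain	0.458
chebyshev	precision	brain	0.452
hamming	precision	brain	0.445
canberra	precision	brain	0.466
bray_curtis	precision	brain	0.45
fisher	recall	brain	0.387
sobolev	recall	brain	0.46
clark	recall	brain	0.414
bhattacharyya	recall	brain	0.398
soergel	recall	brain	0.444
hassanat	recall	brain	0.46
euclidean	recall	brain	0.455
manhattan	recall	brain	0.461
chebyshev	recall	brain	0.455
hamming	recall	brain	0.461
canberra	recall	brain	0.457
bray_curtis	recall	brain	0.445
fisher	f1	brain	0.378
sobolev	f1	brain	0.441
clark	f1	brain	0.404
bhattacharyya	f1	brain	0.394
soergel	f1	brain	0.428
hassanat	f1	brain	0.443
euclidean	f1	brain	0.432
manhattan	f1	brain	0.44
chebyshev	f1	brain	0.438
hamming	f1	brain	0.432
canberra	f1	brain	0.448
bray_curtis	f1	brain	0.428
fisher	accuracy	brain	0.487
sobolev	accuracy	brain	0.526
clark	accuracy	brain	0.493
bhattacharyya	accuracy	brain	0.492
soergel	accuracy	brain	0.518
hassanat	accuracy	brain	0.529
euclidean	accuracy	brain	0.522
manhattan	accuracy	brain	0.524
chebyshev	accuracy	brain	0.521
hamming	accuracy	brain	0.52
canberra	accuracy	brain	0.527
bray_curtis	accuracy	brain	0.518
fisher	precision	breast	0.896
sobolev	precision	breast	0.964
clark	precision	breast	0.967
bhattacharyya	precision	breast	0.905
soergel	precision	breast	0.964
hassanat	precision	breast	0.963
euclidean	precision	breast	0.966
manhattan	precision	breast	0.963
chebyshev	precision	breast	0.963
hamming	precision	breast	0.95
canberra	precision	breast	0.966
bray_curtis	precision	breast	0.969
fisher	recall	breast	0.896
sobolev	recall	breast	0.958
clark	recall	breast	0.972
bhattacharyya	recall	breast	0.895
soergel	recall	breast	0.966
hassanat	recall	breast	0.966
euclidean	recall	breast	0.962
manhattan	recall	breast	0.954
chebyshev	recall	breast	0.961
hamming	recall	breast	0.925
canberra	recall	breast	0.969
bray_curtis	recall	breast	0.969
fisher	f1	breast	0.892
sobolev	f1	breast	0.96
clark	f1	breast	0.969
bhattacharyya	f1	breast	0.896
soergel	f1	breast	0.964
hassanat	f1	breast	0.964
euclidean	f1	breast	0.963
manhattan	f1	breast	0.957
chebyshev	f1	breast	0.96
hamming	f1	breast	0.934
canberra	f1	breast	0.967
bray_curtis	f1	breast	0.968
fisher	accuracy	breast	0.903
sobolev	accuracy	breast	0.964
clark	accuracy	breast	0.971
bhattacharyya	accuracy	breast	0.907
soergel	accuracy	breast	0.967
hassanat	accuracy	breast	0.967
euclidean	accuracy	breast	0.967
manhattan	accuracy	breast	0.962
chebyshev	accuracy	breast	0.964
hamming	accuracy	breast	0.943
canberra	accuracy	breast	0.97
bray_curtis	accuracy	breast	0.971
fisher	precision	lung	0.611
sobolev	precision	lung	0.65
clark	precision	lung	0.144
bhattacharyya	precision	lung	0.553
soergel	precision	lung	0.55
hassanat	precision	lung	0.489
euclidean	precision	lung	0.617
manhattan	precision	lung	0.618
chebyshev	precision	lung	0.268
hamming	precision	lung	0.449
canberra	precision	lung	0.584
bray_curtis	precision	lung	0.55
fisher	recall	lung	0.656
sobolev	recall	lung	0.633
clark	recall	lung	0.356
bhattacharyya	recall	lung	0.6
soergel	recall	lung	0.578
hassanat	recall	lung	0.544
euclidean	recall	lung	0.633
manhattan	recall	lung	0.611
chebyshev	recall	lung	0.389
hamming	recall	lung	0.5
canberra	recall	lung	0.544
bray_curtis	recall	lung	0.578
fisher	f1	lung	0.602
sobolev	f1	lung	0.602
clark	f1	lung	0.198
bhattacharyya	f1	lung	0.511
soergel	f1	lung	0.522
hassanat	f1	lung	0.464
euclidean	f1	lung	0.582
manhattan	f1	lung	0.582
chebyshev	f1	lung	0.262
hamming	f1	lung	0.418
canberra	f1	lung	0.503
bray_curtis	f1	lung	0.522
fisher	accuracy	lung	0.613
sobolev	accuracy	lung	0.618
clark	accuracy	lung	0.307
bhattacharyya	accuracy	lung	0.545
soergel	accuracy	lung	0.545
hassanat	accuracy	lung	0.516
euclidean	accuracy	lung	0.59
manhattan	accuracy	lung	0.585
chebyshev	accuracy	lung	0.351
hamming	accuracy	lung	0.459
canberra	accuracy	lung	0.507
bray_curtis	accuracy	lung	0.545
fisher	precision	prostate	0.868
sobolev	precision	prostate	0.856
clark	precision	prostate	0.892
bhattacharyya	precision	prostate	0.864
soergel	precision	prostate	0.836
hassanat	precision	prostate	0.864
euclidean	precision	prostate	0.856
manhattan	precision	prostate	0.846
chebyshev	precision	prostate	0.864
hamming	precision	prostate	0.625
canberra	precision	prostate	0.926
bray_curtis	precision	prostate	0.836
fisher	recall	prostate	0.792
sobolev	recall	prostate	0.832
clark	recall	prostate	0.836
bhattacharyya	recall	prostate	0.783
soergel	recall	prostate	0.82
hassanat	recall	prostate	0.835
euclidean	recall	prostate	0.845
manhattan	recall	prostate	0.828
chebyshev	recall	prostate	0.845
hamming	recall	prostate	0.625
canberra	recall	prostate	0.882
bray_curtis	recall	prostate	0.82
fisher	f1	prostate	0.769
sobolev	f1	prostate	0.823
clark	f1	prostate	0.84
bhattacharyya	f1	prostate	0.755
soergel	f1	prostate	0.812
hassanat	f1	prostate	0.829
euclidean	f1	prostate	0.834
manhattan	f1	prostate	0.821
chebyshev	f1	prostate	0.834
hamming	f1	prostate	0.594
canberra	f1	prostate	0.877
bray_curtis	f1	prostate	0.812
fisher	accuracy	prostate	0.813
sobolev	accuracy	prostate	0.832
clark	accuracy	prostate	0.861
bhattacharyya	accuracy	prostate	0.803
soergel	accuracy	prostate	0.822
hassanat	accuracy	prostate	0.841
euclidean	accuracy	prostate	0.841
manhattan	accuracy	prostate	0.832
chebyshev	accuracy	prostate	0.841
hamming	accuracy	prostate	0.598
canberra	accuracy	prostate	0.892
bray_curtis	accuracy	prostate	0.822
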