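16 10
AA 1.35964 -0.01133 -0.30011 0.14953 -0.10486 -1.79177 -0.63983 -1.05538 0.82897 0.71177
AC -1.69919 -1.00636 0.70785 1.08390 0.50336 0.08559 1.90537 1.93898 -0.35394 0.83861
AG 0.36621 -0.26501 -1.12356 -0.03603 1.47964 1.05725 1.31240 0.15378 0.12738 -1.00388
AT 0.10619 0.02934 0.00188 1.23421 -0.89551 -0.14951 -0.62492 0.91992 0.27617 -0.63873
CA 1.52961 -2.91302 -0.71741 0.34524 1.75075 -0.85170 -1.46353 -1.41841 -0.34672 -0.76814
CC -1.35965 0.06508 -1.12087 -0.17110 -1.59397 0.39549 -0.61026 -1.18800 -1.30774 0.97900
CG 0.56808 -1.48895 0.30309 0.72958 1.41885 0.05091 1.40135 -0.75692 0.73488 0.85182
CT 0.02607 -1.83493 0.19262 -1.17276 0.83806 1.07595 -0.17064 -1.83072 -1.72842 -1.10575
GA -0.60508 -0.53113 0.49169 -1.23610 -0.86647 -0.56418 0.41684 -0.21459 0.48658 1.97874
GC 1.56878 1.07101 1.08281 2.35084 2.07794 0.00253 -0.43356 0.45619 -0.01760 0.12403
GG 0.02913 -0.44456 -0.24387 0.55973 -0.14128 -0.36657 1.37895 -1.12700 1.43969 2.33886
GT -1.17243 -0.61836 0.63613 2.45244 0.02937 0.09102 -1.12503 -0.08636 -0.22676 -0.51381
TA 0.79881 0.25193 0.39788 -0.18451 0.55778 -1.42727 -0.59802 -2.11539 -1.81292 -0.52512
TC -2.69728 -0.66457 0.76586 -0.96564 0.39169 0.63608 -0.15811 1.45854 -1.19589 0.77887
TG -0.67830 1.57672 0.46484 -0.95884 -2.27154 -0.97572 0.45077 0.91344 -0.73798 1.29585
TT -1.27289 0.19706 -2.01562 0.21921 -1.22571 -0.35366 0.19724 -0.85121 0.39330 0.03917
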