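synthetic coarse-grained bilayer (memflex generator, seed 2024), t= 0.000
  128
    1SYNT   PO4    1   1.114   0.564  12.355
    1SYNT   C4A    2   1.078   0.108  10.927
    2SYNT   PO4    3   2.351   1.228  12.297
    2SYNT   C4A    4   2.333   0.906  10.832
    3SYNT   PO4    5   4.317   0.979  12.654
    3SYNT   C4A    6   4.668   1.089  11.200
    4SYNT   PO4    7   5.998   0.984  12.424
    4SYNT   C4A    8   6.215   0.668  10.974
    5SYNT   PO4    9   7.464   0.462  12.506
    5SYNT   C4A   10   7.180   0.219  11.053
    6SYNT   PO4   11   9.335   1.222  12.361
    6SYNT   C4A   12   9.356   1.463  10.881
    7SYNT   PO4   13   0.763   2.102  11.604
    7SYNT   C4A   14   0.959   2.125  10.117
    8SYNT   PO4   15   2.336   2.623  12.007
    8SYNT   C4A   16   2.317   2.455  10.516
    9SYNT   PO4   17   4.480   2.811  12.721
    9SYNT   C4A   18   4.454   2.688  11.226
   10SYNT   PO4   19   5.516   2.842  12.501
   10SYNT   C4A   20   5.589   2.685  11.011
   11SYNT   PO4   21   7.835   2.603  12.004
   11SYNT   C4A   22   8.002   2.790  10.525
   12SYNT   PO4   23   9.544   2.410  11.197
   12SYNT   C4A   24   9.759   2.865   9.784
   13SYNT   PO4   25   1.003   4.460  11.986
   13SYNT   C4A   26   1.004   4.510  10.487
   14SYNT   PO4   27   2.513   4.123  11.829
   14SYNT   C4A   28   2.064   4.013  10.402
   15SYNT   PO4   29   4.125   4.096  11.574
   15SYNT   C4A   30   3.634   4.032  10.158
   16SYNT   PO4   31   6.119   3.983  12.097
   16SYNT   C4A   32   5.938   3.436  10.712
   17SYNT   PO4   33   7.175   4.295  12.559
   17SYNT   C4A   34   6.997   3.814  11.150
   18SYNT   PO4   35   9.469   4.292  11.913
   18SYNT   C4A   36   9.591   4.590  10.448
   19SYNT   PO4   37   0.526   5.468  11.933
   19SYNT   C4A   38   0.758   5.492  10.451
   20SYNT   PO4   39   2.330   6.034  12.459
   20SYNT   C4A   40   2.411   5.912  10.966
   21SYNT   PO4   41   3.789   5.794  11.794
   21SYNT   C4A   42   3.716   5.901  10.300
   22SYNT   PO4   43   5.510   5.825  11.654
   22SYNT   C4A   44   5.485   5.656  10.164
   23SYNT   PO4   45   7.650   6.044  11.856
   23SYNT   C4A   46   7.691   5.790  10.378
   24SYNT   PO4   47   9.458   6.013  11.331
   24SYNT   C4A   48   9.824   5.969   9.877
   25SYNT   PO4   49   1.081   7.100  12.306
   25SYNT   C4A   50   1.307   6.914  10.834
   26SYNT   PO4   51   2.327   7.243  12.656
   26SYNT   C4A   52   2.575   7.191  11.177
   27SYNT   PO4   53   4.263   7.464  11.733
   27SYNT   C4A   54   4.572   7.967  10.354
   28SYNT   PO4   55   6.096   7.315  12.073
   28SYNT   C4A   56   6.212   7.447  10.583
   29SYNT   PO4   57   7.084   7.146  11.684
   29SYNT   C4A   58   7.172   7.117  10.187
   30SYNT   PO4   59   8.768   7.439  11.897
   30SYNT   C4A   60   8.712   7.683  10.418
   31SYNT   PO4   61   0.784   9.060  12.202
   31SYNT   C4A   62   0.434   8.953  10.747
   32SYNT   PO4   63   2.325   9.283  12.401
   32SYNT   C4A   64   2.177   9.247  10.909
   33SYNT   PO4   65   0.672   1.032   8.174
   33SYNT   C4A   66   0.397   0.878   9.641
   34SYNT   PO4   67   2.762   0.839   8.402
   34SYNT   C4A   68   2.749   0.936   9.899
   35SYNT   PO4   69   4.488   1.228   8.538
   35SYNT   C4A   70   4.310   1.340  10.024
   36SYNT   PO4   71   6.016   0.892   8.564
   36SYNT   C4A   72   6.037   0.795  10.061
   37SYNT   PO4   73   7.341   0.658   8.635
   37SYNT   C4A   74   7.716   0.693  10.087
   38SYNT   PO4   75   8.989   0.976   8.221
   38SYNT   C4A   76   9.126   0.848   9.709
   39SYNT   PO4   77   0.960   2.268   8.630
   39SYNT   C4A   78   0.893   2.362  10.126
   40SYNT   PO4   79   2.249   2.525   7.475
   40SYNT   C4A   80   2.212   3.011   8.894
   41SYNT   PO4   81   4.277   2.299   8.071
   41SYNT   C4A   82   4.250   2.869   9.458
   42SYNT   PO4   83   5.787   2.770   8.303
   42SYNT   C4A   84   5.603   2.853   9.789
   43SYNT   PO4   85   7.344   2.210   8.013
   43SYNT   C4A   86   7.421   2.336   9.506
   44SYNT   PO4   87   9.340   2.137   8.167
   44SYNT   C4A   88   9.429   2.200   9.663
   45SYNT   PO4   89   0.653   3.957   8.191
   45SYNT   C4A   90   0.674   3.854   9.688
   46SYNT   PO4   91   2.113   4.419   7.623
   46SYNT   C4A   92   2.304   4.417   9.111
   47SYNT   PO4   93   4.305   3.813   7.592
   47SYNT   C4A   94   4.224   4.117   9.059
   48SYNT   PO4   95   5.600   4.266   7.924
   48SYNT   C4A   96   5.287   4.173   9.387
   49SYNT   PO4   97   7.243   4.429   8.276
   49SYNT   C4A   98   7.232   4.469   9.775
   50SYNT   PO4   99   8.954   3.823   8.125
   50SYNT   C4A  100   9.011   4.008   9.612
   51SYNT   PO4  101   0.832   5.755   7.758
   51SYNT   C4A  102   0.793   5.499   9.235
   52SYNT   PO4  103   2.098   6.169   8.166
   52SYNT   C4A  104   2.237   6.145   9.660
   53SYNT   PO4  105   4.325   6.118   7.704
   53SYNT   C4A  106   4.333   6.024   9.201
   54SYNT   PO4  107   5.819   5.557   7.018
   54SYNT   C4A  108   5.691   5.134   8.452
   55SYNT   PO4  109   7.896   5.823   8.010
   55SYNT   C4A  110   7.918   5.923   9.506
   56SYNT   PO4  111   9.007   5.634   7.963
   56SYNT   C4A  112   8.886   5.736   9.455
   57SYNT   PO4  113   0.513   7.870   8.155
   57SYNT   C4A  114   0.413   7.739   9.646
   58SYNT   PO4  115   2.799   7.136   8.152
   58SYNT   C4A  116   2.885   7.402   9.626
   59SYNT   PO4  117   4.210   7.754   7.679
   59SYNT   C4A  118   4.206   7.804   9.178
   60SYNT   PO4  119   6.174   7.185   8.110
   60SYNT   C4A  120   6.150   7.157   9.609
   61SYNT   PO4  121   7.607   7.671   7.702
   61SYNT   C4A  122   7.714   7.993   9.163
   62SYNT   PO4  123   8.783   7.096   8.256
   62SYNT   C4A  124   8.796   7.473   9.707
   63SYNT   PO4  125   1.040   9.225   8.135
   63SYNT   C4A  126   0.984   8.743   9.555
   64SYNT   PO4  127   2.236   9.427   8.041
   64SYNT   C4A  128   2.207   9.085   9.501
  10.00000  10.00000  20.00000
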